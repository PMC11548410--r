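# Finite-difference verification of the network engine's backward passes.

ns <- asNamespace("reachsynth")

fd_check <- function(net, x, dout_fn = function(o) 2 * o, eps = 1e-6) {
  lossf <- function(net, x) {
    o <- ns$net_forward(net, x, training = FALSE)$out
    sum(o^2)
  }
  fw <- ns$net_forward(net, x, training = FALSE)
  bk <- ns$net_backward(net, fw$caches, dout_fn(fw$out))
  num_dx <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num_dx[i] <- (lossf(net, xp) - lossf(net, xm)) / (2 * eps)
  }
  errs <- max(abs(num_dx - bk$dx))
  for (li in seq_along(net$layers)) {
    ps <- net$layers[[li]]$params
    if (is.null(ps)) next
    for (pn in names(ps)) {
      p0 <- ps[[pn]]
      num <- p0 * 0
      for (i in seq_along(p0)) {
        n2 <- net; n2$layers[[li]]$params[[pn]][i] <- p0[i] + eps
        up <- lossf(n2, x)
        n2$layers[[li]]$params[[pn]][i] <- p0[i] - eps
        dn <- lossf(n2, x)
        num[i] <- (up - dn) / (2 * eps)
      }
      errs <- max(errs, max(abs(num - bk$grads[[li]][[pn]])))
    }
  }
  errs
}

test_that("conv / pool / upsample / dense backward passes match finite differences", {
  set.seed(101)
  net <- list(layers = list(
    ns$nn_conv1d(3L, 4L, 5L, 1L), ns$nn_lrelu(0.2),
    ns$nn_conv1d(4L, 3L, 3L, 2L), ns$nn_relu(),
    ns$nn_maxpool2(), ns$nn_upsample2(),
    ns$nn_flatten(), ns$nn_dense(3L * 8L, 2L)
  ))
  x <- array(rnorm(2 * 16 * 3), c(2, 16, 3))
  expect_lt(fd_check(net, x), 1e-6)
})

test_that("batch-norm backward matches finite differences in inference mode", {
  set.seed(102)
  net <- list(layers = list(
    ns$nn_dense(5L, 6L), ns$nn_bn(6L), ns$nn_relu(), ns$nn_dense(6L, 2L)
  ))
  # give running stats non-trivial values first
  x0 <- matrix(rnorm(40 * 5), 40, 5)
  net <- ns$net_forward(net, x0, training = TRUE)$net
  x <- matrix(rnorm(3 * 5), 3, 5)
  expect_lt(fd_check(net, x), 1e-6)
})

test_that("minibatch discrimination layer backward matches finite differences", {
  set.seed(103)
  net <- list(layers = list(
    ns$nn_dense(4L, 6L), ns$nn_minibatch(6L, 3L, 2L), ns$nn_dense(9L, 1L)
  ))
  x <- matrix(rnorm(4 * 4), 4, 4)
  expect_lt(fd_check(net, x), 1e-6)
})

test_that("training-mode batch-norm gradient is exact for a direct loss", {
  set.seed(104)
  layer <- ns$nn_bn(3L)
  x <- matrix(rnorm(6 * 3), 6, 3)
  fw <- ns$bn_forward(layer, x, training = TRUE)
  bk <- ns$bn_backward(fw$layer, fw$cache, 2 * fw$out)
  lossf <- function(x) sum(ns$bn_forward(layer, x, training = TRUE)$out^2)
  eps <- 1e-6
  num <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num[i] <- (lossf(xp) - lossf(xm)) / (2 * eps)
  }
  expect_lt(max(abs(num - bk$dx)), 1e-5)
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(105)
  logits <- matrix(rnorm(4 * 3), 4, 3)
  y <- c(1L, 3L, 2L, 1L)
  sx <- ns$softmax_xent(logits, y)
  eps <- 1e-6
  num <- logits * 0
  for (i in seq_along(logits)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num[i] <- (ns$softmax_xent(lp, y)$loss - ns$softmax_xent(lm, y)$loss) /
      (2 * eps)
  }
  expect_lt(max(abs(num - sx$dlogits)), 1e-7)
  expect_equal(rowSums(sx$probs), rep(1, 4))
})
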