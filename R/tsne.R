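# Exact (O(N^2)) t-SNE, sufficient for the few-hundred-trial embeddings this
# package produces. Standard recipe: perplexity calibration by bisection,
# symmetrized affinities, early exaggeration, momentum gradient descent with
# adaptive gains.

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    row <- numeric(n)
    row[-i] <- p / sum(p)
    P[i, ] <- row
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_run <- function(X, perplexity = 30, max_iter = 400, eta = 200,
                     exaggeration = 12, exag_iter = 100) {
  n <- nrow(X)
  P <- tsne_p_matrix(X, perplexity) * exaggeration
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == exag_iter) P <- P / exaggeration
    if (iter == 20) momentum <- 0.8
  }
  Y
}

#' Embed real and synthetic trials with t-SNE
#'
#' Flattens each trial into a 2700-dimensional vector after per-channel
#' standardization over the combined data, reduces to at most 50 principal
#' components, and runs t-SNE to two dimensions. The embedding gives a
#' qualitative check of whether synthetic trials occupy the same regions as
#' real trials of the same task and impairment level.
#'
#' @param real,synth `trial_dataset`s (either may be `NULL`).
#' @param seed Integer seed (t-SNE is stochastic).
#' @param perplexity Target perplexity; lowered to `N / 4` for small N.
#' @param max_iter Gradient-descent iterations.
#' @return A `tsne_embedding` tibble: `dim1`, `dim2`, `task`, `group`,
#'   `provenance`.
#' @export
tsne_embed <- function(real, synth = NULL, seed = 1, perplexity = 30,
                       max_iter = 400) {
  ds <- if (is.null(synth)) as_tibble(real) else
    bind_rows(as_tibble(real), as_tibble(synth))
  n <- nrow(ds)
  if (n < 12L) {
    abort("Need at least 12 trials to embed.",
          class = "reachsynth_invalid_input")
  }
  perplexity <- min(perplexity, floor(n / 4))
  X <- t(vapply(ds$signal, function(s) as.numeric(s), numeric(.TRIAL_LEN * 9)))
  # per-channel standardization over the combined data
  for (c in 1:9) {
    cols <- ((c - 1) * .TRIAL_LEN + 1):(c * .TRIAL_LEN)
    mu <- mean(X[, cols]); sdv <- max(sd(X[, cols]), 1e-12)
    X[, cols] <- (X[, cols] - mu) / sdv
  }
  set.seed(as.integer(seed))
  k <- min(50L, n - 1L, ncol(X))
  pc <- prcomp(X, rank. = k, center = TRUE, scale. = FALSE)
  Y <- tsne_run(pc$x, perplexity = perplexity, max_iter = max_iter)
  out <- tibble(
    dim1 = Y[, 1], dim2 = Y[, 2],
    task = ds$task, group = ds$group, provenance = ds$provenance
  )
  class(out) <- c("tsne_embedding", class(out))
  out
}
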