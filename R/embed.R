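#' t-SNE embedding of a precomputed similarity matrix
#'
#' Standard t-distributed stochastic neighbour embedding, taking the
#' given nonnegative symmetric similarity directly as the joint affinity
#' distribution P (after zeroing the diagonal, symmetrising and
#' normalising to sum 1) instead of computing perplexity-calibrated
#' affinities from raw features. The embedding minimises the
#' Kullback-Leibler divergence between P and the Student-t kernel of the
#' embedded points by gradient descent with momentum, adaptive gains and
#' an early-exaggeration phase, the reference recipe for t-SNE
#' optimisation.
#'
#' Initialisation is spectral by default (leading non-trivial
#' eigenvectors of the affinity, scaled to sd 1e-4), which makes the
#' embedding deterministic without a seed; `init = "random"` draws a
#' Gaussian start from the current RNG state.
#'
#' @param P Nonnegative square matrix of similarities/affinities.
#' @param dims Output dimensionality (default 2).
#' @param max_iter Gradient-descent iterations.
#' @param eta Learning rate.
#' @param exaggeration,exaggeration_iter Early-exaggeration factor and
#'   duration.
#' @param momentum,final_momentum,momentum_switch Momentum schedule.
#' @param init `"spectral"` (deterministic) or `"random"`.
#' @return An N x `dims` matrix of coordinates.
#' @export
similarity_tsne <- function(P, dims = 2, max_iter = 400, eta = 200,
                            exaggeration = 4, exaggeration_iter = 100,
                            momentum = 0.5, final_momentum = 0.8,
                            momentum_switch = 250,
                            init = c("spectral", "random")) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P), all(P >= 0))
  init <- match.arg(init)
  n <- nrow(P)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  s <- sum(P)
  if (s <= 0) stop("affinity matrix has no off-diagonal mass")
  P <- P / s
  P[P < 1e-12] <- 1e-12
  P <- P / sum(P)

  Y <- switch(init,
    spectral = {
      D <- rowSums(P)
      W <- P / sqrt(D)
      W <- t(t(W) / sqrt(D))
      e <- eigen((W + t(W)) / 2, symmetric = TRUE)
      V <- e$vectors[, 1L + seq_len(dims), drop = FALSE]
      V <- sweep(V, 2, colMeans(V))
      sdv <- pmax(apply(V, 2, stats::sd), .Machine$double.eps)
      1e-4 * sweep(V, 2, sdv, "/")
    },
    random = matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  )
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  P4 <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pit <- if (iter <= exaggeration_iter) P4 else P
    sq <- rowSums(Y * Y)
    Dm <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
    Qnum <- 1 / (1 + Dm)
    diag(Qnum) <- 0
    Qn <- Qnum / sum(Qnum)
    W <- (Pit - Qn) * Qnum
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter < momentum_switch) momentum else final_momentum
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Euclidean-distance baseline affinity
#'
#' A simple similarity matrix built directly from Euclidean distances in
#' the raw feature space: a Gaussian kernel with a single global
#' bandwidth equal to the mean pairwise distance. Serves as the baseline
#' against which the learned multi-kernel similarity is compared (the
#' learned similarity separates planted clusters in the embedding; the
#' Euclidean affinity typically does not).
#'
#' @param x Numeric matrix (subjects x features).
#' @return An N x N symmetric nonnegative matrix with zero diagonal.
#' @export
euclidean_similarity <- function(x) {
  stopifnot(is.matrix(x))
  d <- as.matrix(stats::dist(x))
  bw <- mean(d[upper.tri(d)])
  if (bw <= 0) stop("all subjects identical; no distance scale")
  s <- exp(-(d / bw)^2 / 2)
  diag(s) <- 0
  s
}
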