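#' Multi-kernel similarity learning with block-structure constraint
#'
#' Fits the similarity-learning model at the heart of the package. Given a
#' subjects-by-markers matrix, a bank of per-marker Gaussian kernels
#' \eqn{K_q} is combined with nonnegative weights \eqn{w} (summing to 1)
#' into a learned row-stochastic similarity matrix \eqn{S}, by minimising
#'
#' \deqn{-\sum_q w_q \langle K_q, S\rangle
#'   + \gamma\,\mathrm{tr}(A^\top (I - S) A)
#'   + \mu \sum_q w_q \log w_q + \beta \|S\|_F^2}
#'
#' subject to \eqn{A^\top A = I_C}, \eqn{w \ge 0}, \eqn{\sum w = 1},
#' \eqn{S \ge 0} and unit row sums. The trace term pushes the graph
#' Laplacian of \eqn{S} towards rank deficiency of order C, i.e. a
#' C-block structure; the entropy term keeps more than one kernel active;
#' the Frobenius term controls the scale of \eqn{S}.
#'
#' The optimisation alternates three exact subproblem solutions from a
#' deterministic start (uniform weights, S the row-normalised average
#' kernel):
#' \enumerate{
#'   \item A-step: the C eigenvectors of \eqn{I - (S + S^\top)/2} with
#'     smallest eigenvalues;
#'   \item w-step: the closed-form entropy-regularised update
#'     \eqn{w_q \propto \exp(\langle K_q, S\rangle/\mu)};
#'   \item S-step: per row, the Euclidean projection of
#'     \eqn{(\sum_q w_q K_q + \gamma A A^\top)_i / (2\beta)} onto the
#'     probability simplex, which is the exact minimiser of the row
#'     subproblem. Self-similarity is constrained to zero (no
#'     self-edges): without this, the kernel diagonal — the largest
#'     entry of every Gaussian kernel — soaks up the row's simplex mass
#'     and the learned graph degenerates towards the identity.
#' }
#' Because every step solves its subproblem exactly, the objective is
#' non-increasing across cycles (up to numerical tolerance).
#'
#' After convergence the symmetrised similarity is embedded with t-SNE
#' ([similarity_tsne()]) and cluster labels are assigned by k-means with
#' multiple restarts on the embedding; with `embed = FALSE` the k-means
#' runs on the rows of \eqn{A} (the spectral representation), which is
#' much faster and is used by the bootstrap stability loop.
#'
#' @param x Numeric matrix (subjects x markers), or a prebuilt
#'   [kernel_bank()].
#' @param clusters Number of clusters C (at least 2, at most N/2).
#' @param k,sigma Kernel grids, passed to [kernel_bank()] when `x` is a
#'   matrix: neighbourhood sizes scaled to the cohort by default, and
#'   the reference bandwidth multipliers 30-50, whose smooth kernels
#'   average out uninformative markers in the weighted combination.
#' @param gamma Block-structure weight. Default (`NULL`): scaled so the
#'   trace term's gradient matches the kernel term's at the start,
#'   `mean(K w) * N / C`.
#' @param beta Frobenius penalty. Default: 0.8 times the mean
#'   off-diagonal entry of the average kernel.
#' @param entropy Entropy weight \eqn{\mu}. Default: ten times the
#'   standard deviation of the initial kernel-similarity inner products
#'   \eqn{\langle K_q, S_0\rangle}, a temperature that keeps a soft
#'   spread of weight over the best-matching kernels (rather than a
#'   single winner or a uniform smear) regardless of cohort size and
#'   kernel scaling. Cluster recovery is insensitive to this choice over
#'   two orders of magnitude; the spread mainly affects how sharply
#'   marker importances concentrate.
#' @param normalize Kernel normalisation, passed to [kernel_bank()].
#' @param scale If `TRUE` (default) min-max scale `x` first.
#' @param max_iter,tol Stop after `max_iter` cycles or when the relative
#'   objective change drops below `tol`.
#' @param embed Compute the t-SNE embedding and cluster on it (default);
#'   otherwise cluster on the spectral representation A.
#' @param dims Embedding dimensionality.
#' @param nstart k-means restarts.
#' @param seed Optional seed for the embedding initialisation and
#'   k-means; fixing it makes labels reproducible.
#' @param tsne_args Named list of extra arguments to [similarity_tsne()].
#'
#' @return An object of class `"cimlr"`: list with `S` (N x N learned
#'   similarity, row-stochastic), `A` (N x C, orthonormal columns), `w`
#'   (kernel weights), `weights` (data frame: marker, k, sigma, weight),
#'   `objective` (per-cycle trace), `labels` (integer cluster per subject,
#'   relabelled by decreasing cluster size), `embedding` (N x dims or
#'   `NULL`), `clusters`, `converged`, `iterations`, the resolved
#'   `gamma`/`beta`/`entropy`, `subject_ids`, `marker_ids`, and `call`.
#'
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 60, n_markers = 25,
#'                                      n_informative = 6, n_regions = 10,
#'                                      n_clusters = 2,
#'                                      cluster_proportions = c(.5, .5),
#'                                      seed = 3))
#' fit <- cimlr(coh$markers, clusters = 2, embed = FALSE, seed = 1)
#' table(fit$labels, coh$true_cluster)
#' @seealso [cimlr_objective()], [estimate_clusters()], [cluster_stability()]
#' @export
cimlr <- function(x, clusters = 4,
                  k = NULL,
                  sigma = sigma_grid("wide")$sigma,
                  gamma = NULL, beta = NULL, entropy = NULL,
                  normalize = c("spectral", "scale", "none"),
                  scale = TRUE, max_iter = 50, tol = 1e-5,
                  embed = TRUE, dims = 2, nstart = 50, seed = NULL,
                  tsne_args = list()) {
  cl_match <- match.call()
  if (inherits(x, "kernel_bank")) {
    bank <- x
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    if (scale) x <- minmax_scale(x)
    bank <- kernel_bank(x, k = k, sigma = sigma,
                        normalize = match.arg(normalize))
  }
  n <- bank$n
  C <- as.integer(clusters)
  if (C < 2L) stop("'clusters' must be at least 2")
  if (n < 2L * C) stop("need at least 2 * clusters subjects")
  KM <- bank$kernels
  Q <- ncol(KM)

  # deterministic initialisation (no self-edges)
  w <- rep(1 / Q, Q)
  Kw <- matrix(KM %*% w, n, n)
  S <- Kw
  diag(S) <- 0
  S <- S / rowSums(S)
  v <- drop(crossprod(KM, as.vector(S)))
  if (is.null(beta)) beta <- 0.8 * mean(Kw[row(Kw) != col(Kw)])
  if (is.null(gamma)) gamma <- mean(Kw) * n / C
  if (is.null(entropy)) entropy <- max(10 * stats::sd(v), 1e-12)
  stopifnot(gamma > 0, beta > 0, entropy > 0)

  A <- .smallest_eigenvectors(diag(n) - (S + t(S)) / 2, C)
  obj <- .cimlr_objective_terms(S, A, w, v, gamma, beta, entropy, C)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- .smallest_eigenvectors(diag(n) - (S + t(S)) / 2, C)
    w <- .softmax(v / entropy)
    Kw <- matrix(KM %*% w, n, n)
    G <- (Kw + gamma * tcrossprod(A)) / (2 * beta)
    S <- .project_rows_simplex(G)
    v <- drop(crossprod(KM, as.vector(S)))
    new_obj <- .cimlr_objective_terms(S, A, w, v, gamma, beta, entropy, C)
    if (!is.finite(new_obj))
      stop("objective became non-finite at iteration ", it)
    trace[it + 1L] <- new_obj
    if (abs(new_obj - obj) <= tol * abs(obj)) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  trace <- trace[seq_len(it + 1L)]

  fit <- structure(list(
    S = `dimnames<-`(S, list(bank$subject_ids, bank$subject_ids)),
    A = A, w = w,
    weights = data.frame(bank$params[, c("marker", "k", "sigma")],
                         weight = w),
    objective = trace, labels = NULL, embedding = NULL,
    clusters = C, converged = converged, iterations = it,
    gamma = gamma, beta = beta, entropy = entropy,
    subject_ids = bank$subject_ids, marker_ids = bank$marker_ids,
    call = cl_match
  ), class = "cimlr")

  embed_and_cluster(fit, embed = embed, dims = dims, nstart = nstart,
                    seed = seed, tsne_args = tsne_args)
}

#' Embed a learned similarity and assign cluster labels
#'
#' Runs t-SNE on the symmetrised, sum-normalised learned similarity
#' (supplied to the embedding as the precomputed joint affinity, not
#' recomputed from raw features) and clusters the embedding with k-means
#' using multiple restarts; with `embed = FALSE` the k-means runs on the
#' spectral representation A instead. Labels are renumbered by decreasing
#' cluster size (ties by first occurrence) so that numbering is stable.
#'
#' @inheritParams cimlr
#' @param fit A `"cimlr"` object.
#' @return The fit with `embedding` and `labels` filled in.
#' @export
embed_and_cluster <- function(fit, embed = TRUE, dims = 2, nstart = 50,
                              seed = NULL, tsne_args = list()) {
  stopifnot(inherits(fit, "cimlr"))
  if (!is.null(seed)) set.seed(seed)
  if (embed) {
    P <- fit$S + t(fit$S)
    fit$embedding <- do.call(similarity_tsne,
                             c(list(P, dims = dims), tsne_args))
    rownames(fit$embedding) <- fit$subject_ids
    Y <- fit$embedding
  } else {
    Y <- fit$A
  }
  km <- stats::kmeans(Y, centers = fit$clusters, nstart = nstart,
                      iter.max = 100)
  fit$labels <- stats::setNames(.relabel_by_size(km$cluster),
                                fit$subject_ids)
  fit
}

.relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- integer(length(tab))
  map[as.integer(names(tab))[ord]] <- seq_along(tab)
  map[labels]
}

#' Evaluate the similarity-learning objective
#'
#' Computes the four-term objective minimised by [cimlr()] at arbitrary
#' feasible (or infeasible) points; a pure function used for the
#' convergence trace and in tests.
#'
#' @param S N x N similarity matrix.
#' @param A N x C auxiliary matrix.
#' @param w Kernel weight vector (length Q).
#' @param bank The [kernel_bank()] providing the Q kernels.
#' @param gamma,beta,entropy Term weights (see [cimlr()]).
#' @return A single number.
#' @export
cimlr_objective <- function(S, A, w, bank, gamma, beta, entropy) {
  stopifnot(inherits(bank, "kernel_bank"))
  n <- bank$n
  if (!is.matrix(S) || any(dim(S) != n))
    stop("'S' must be ", n, " x ", n)
  if (!is.matrix(A) || nrow(A) != n) stop("'A' must have ", n, " rows")
  if (length(w) != ncol(bank$kernels))
    stop("'w' must have one weight per kernel")
  v <- drop(crossprod(bank$kernels, as.vector(S)))
  .cimlr_objective_terms(S, A, w, v, gamma, beta, entropy, ncol(A))
}

.cimlr_objective_terms <- function(S, A, w, v, gamma, beta, entropy, C) {
  wl <- w * log(w)
  wl[w == 0] <- 0
  trAIS <- sum(A * A) - sum(A * (S %*% A))  # tr(A'(I - S)A)
  -sum(w * v) + gamma * trAIS + entropy * sum(wl) + beta * sum(S * S)
}

.softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

.smallest_eigenvectors <- function(M, C) {
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, ncol(M) - seq_len(C) + 1L, drop = FALSE]
  # fix sign for determinism: largest-magnitude entry positive
  for (j in seq_len(C)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V[, rev(seq_len(C)), drop = FALSE]
}

# Euclidean projection of each row of G onto the probability simplex
# (sort-based algorithm; exact in O(n log n) per row). The diagonal is
# held at zero: self-similarity is not a free coordinate.
.project_rows_simplex <- function(G) {
  n <- nrow(G)
  S <- matrix(0, n, ncol(G))
  for (i in seq_len(n)) S[i, -i] <- .project_simplex(G[i, -i])
  S
}

.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}
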