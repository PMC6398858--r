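#' Build the multi-kernel bank for a marker matrix
#'
#' For every marker m and every combination of a neighbourhood size k and
#' a bandwidth multiplier sigma, builds the N x N Gaussian kernel
#'
#' \deqn{K(i,j) = \frac{1}{\epsilon_{ij}\sqrt{2\pi}}
#'   \exp\!\left(-\frac{(x_{im}-x_{jm})^2}{2\epsilon_{ij}^2}\right),}
#'
#' with an adaptive pairwise bandwidth
#' \eqn{\epsilon_{ij} = \sigma(\mu_i + \mu_j)/2}, where \eqn{\mu_i} is the
#' mean distance from subject i to its k nearest neighbours in that marker
#' (self excluded, ties broken by subject order). With the default grids
#' (3 values of k, 5 of sigma) each marker contributes P = 15 kernels, so
#' 172 markers yield 2580 kernels.
#'
#' Degenerate bandwidths are guarded: a zero \eqn{\epsilon_{ij}}
#' (duplicated values) is replaced by the smallest positive bandwidth of
#' that marker; a marker that is entirely constant yields uniform kernels
#' with value 1/N, which carry no information and receive vanishing weight
#' during fitting.
#'
#' @param x Numeric matrix (subjects x markers), complete and normally
#'   min-max scaled (see [minmax_scale()]).
#' @param k Integer vector of neighbourhood sizes. The default (`NULL`)
#'   uses 10%, 15% and 17% of the cohort — the fractions corresponding
#'   to the reference sizes \{30, 45, 50\} at N = 298, which the default
#'   reproduces exactly — so that neighbourhoods stay proportionate on
#'   smaller cohorts. Explicit values of at least N are clamped to
#'   N - 1 with a warning when `clamp_k` is `TRUE` (the default),
#'   otherwise they are an error.
#' @param sigma Positive numeric vector of bandwidth multipliers. The
#'   default (`"wide"`) grid uses large multipliers: the resulting
#'   smooth kernels average out uninformative markers in the weighted
#'   combination, while the per-kernel normalisation keeps them
#'   comparable. `sigma_grid("compact")` (multipliers in [1, 2]) gives
#'   sharp bandwidths commensurate with min-max-scaled data; with it,
#'   single noisy markers imprint their own spurious neighbourhood
#'   structure, so it suits data with mostly informative features.
#' @param clamp_k See `k`.
#' @param normalize Per-kernel normalisation applied after Eq-style
#'   construction, making kernels of different markers and bandwidths
#'   comparable in scale before they compete for weight (the standard
#'   practice in multiple-kernel similarity learning): `"spectral"`
#'   (default) rescales each kernel symmetrically by its row sums,
#'   \eqn{D^{-1/2} K D^{-1/2}}; `"scale"` divides each kernel by its mean
#'   entry; `"none"` keeps the raw density values, whose
#'   \eqn{1/(\epsilon\sqrt{2\pi})} prefactor then couples a kernel's
#'   overall magnitude to the marker's local density.
#' @return An object of class `"kernel_bank"`: list with `kernels`
#'   (an N^2 x Q matrix, one vectorised symmetric kernel per column),
#'   `params` (data frame: kernel, marker, k, sigma), `mu` (an
#'   N x M x length(k) array of mean KNN distances), `n`, `subject_ids`,
#'   `marker_ids`.
#' @examples
#' x <- minmax_scale(matrix(rnorm(40), 20, 2,
#'                          dimnames = list(NULL, c("a", "b"))))
#' b <- kernel_bank(x, k = c(3, 5), sigma = c(1, 1.5, 2))
#' nrow(b$params)  # 2 markers x 6 parameterisations = 12 kernels
#' @export
kernel_bank <- function(x, k = NULL,
                        sigma = c(30, 35, 40, 45, 50),
                        clamp_k = TRUE,
                        normalize = c("spectral", "scale", "none")) {
  normalize <- match.arg(normalize)
  if (is.null(k))
    k <- pmax(2L, pmin(as.integer(round(nrow(x) * c(0.1007, 0.151, 0.1678))),
                       nrow(x) - 1L))
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("'x' must not contain missing values")
  n <- nrow(x)
  m <- ncol(x)
  if (n < 3L) stop("need at least 3 subjects")
  stopifnot(all(sigma > 0), all(k >= 1))
  k <- as.integer(k)
  if (any(k >= n)) {
    if (!clamp_k)
      stop("every k must be smaller than the number of subjects (", n, ")")
    warning("k value(s) >= N clamped to N - 1 = ", n - 1L)
    k <- pmin(k, n - 1L)
  }
  marker_ids <- colnames(x)
  if (is.null(marker_ids)) marker_ids <- sprintf("marker_%03d", seq_len(m))
  q_per <- length(k) * length(sigma)
  Q <- m * q_per
  K <- matrix(0, n * n, Q)
  mu <- array(NA_real_, c(n, m, length(k)),
              dimnames = list(rownames(x), marker_ids, paste0("k", k)))
  params <- data.frame(kernel = seq_len(Q),
                       marker = rep(marker_ids, each = q_per),
                       k = rep(rep(k, each = length(sigma)), m),
                       sigma = rep(sigma, length(k) * m),
                       stringsAsFactors = FALSE)
  inv_sqrt2pi <- 1 / sqrt(2 * pi)
  col <- 0L
  for (j in seq_len(m)) {
    d <- abs(outer(x[, j], x[, j], "-"))
    d2 <- d * d
    # distances to the others, ascending per row; the leading 0 is the
    # self distance (duplicated values keep their extra zeros)
    ds <- t(apply(d, 1, sort))[, -1, drop = FALSE]
    cs <- t(apply(ds, 1, cumsum))
    for (ki in seq_along(k)) {
      mu_i <- cs[, k[ki]] / k[ki]
      mu[, j, ki] <- mu_i
      eps0 <- outer(mu_i, mu_i, "+") / 2
      degenerate <- all(eps0 == 0)
      if (!degenerate && any(eps0 == 0))
        eps0[eps0 == 0] <- min(eps0[eps0 > 0])
      e2 <- d2 / (eps0 * eps0)
      for (si in seq_along(sigma)) {
        col <- col + 1L
        if (degenerate) {
          K[, col] <- 1 / n        # constant marker: uninformative kernel
          next
        }
        Kq <- (inv_sqrt2pi / (sigma[si] * eps0)) *
          exp(-e2 / (2 * sigma[si]^2))
        K[, col] <- switch(normalize,
          none = Kq,
          scale = Kq / mean(Kq),
          spectral = {
            dr <- sqrt(rowSums(Kq))
            (Kq / dr) / rep(dr, each = n)
          })
      }
    }
  }
  structure(list(kernels = K, params = params, mu = mu, n = n,
                 subject_ids = rownames(x), marker_ids = marker_ids,
                 k = k, sigma = sigma),
            class = "kernel_bank")
}

#' Predefined kernel parameter grids
#'
#' `"wide"` is the historical grid with large bandwidth multipliers
#' (k in \{30, 45, 50\}, sigma in \{30, 35, 40, 45, 50\}); `"compact"`
#' uses neighbourhoods and multipliers commensurate with min-max-scaled
#' data (k in \{10, 20, 30\}, sigma from 1 to 2 in steps of 0.25 reduced
#' to 5 values). Both define P = 15 kernels per marker.
#'
#' @param name `"wide"` or `"compact"`.
#' @return A list with elements `k` and `sigma`.
#' @export
sigma_grid <- function(name = c("wide", "compact")) {
  name <- match.arg(name)
  switch(name,
         wide = list(k = c(30L, 45L, 50L), sigma = c(30, 35, 40, 45, 50)),
         compact = list(k = c(10L, 20L, 30L),
                        sigma = c(1, 1.25, 1.5, 1.75, 2)))
}

#' Extract one kernel from a bank as a matrix
#'
#' @param bank A [kernel_bank()].
#' @param i Kernel index (row of `bank$params`).
#' @return An N x N symmetric matrix.
#' @export
get_kernel <- function(bank, i) {
  stopifnot(inherits(bank, "kernel_bank"),
            i >= 1, i <= ncol(bank$kernels))
  matrix(bank$kernels[, i], bank$n, bank$n,
         dimnames = list(bank$subject_ids, bank$subject_ids))
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("Kernel bank: %d kernels (%d markers x %d parameterisations), N = %d\n",
              nrow(x$params), length(x$marker_ids),
              length(x$k) * length(x$sigma), x$n))
  invisible(x)
}
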