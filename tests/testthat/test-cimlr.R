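fit_small <- function(coh = small_cohort(), ...) {
  cimlr(coh$markers, clusters = coh$config$n_clusters, embed = FALSE,
        seed = 1, ...)
}

test_that("a fitted model satisfies every constraint of the program", {
  coh <- small_cohort()
  fit <- fit_small(coh)
  expect_true(all(fit$S >= 0))
  expect_equal(rowSums(fit$S), rep(1, nrow(fit$S)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(fit$w >= 0))
  expect_equal(sum(fit$w), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$A), diag(fit$clusters), tolerance = 1e-6,
               ignore_attr = TRUE)
  # alternating exact minimisation: the objective never increases
  expect_true(all(diff(fit$objective) <=
                    1e-5 * abs(fit$objective[-length(fit$objective)]) +
                    1e-12))
  expect_true(fit$converged)
})

test_that("the objective evaluates the four terms exactly", {
  set.seed(7)
  x <- minmax_scale(matrix(runif(9), 3, 3,
                           dimnames = list(NULL, paste0("m", 1:3))))
  bank <- kernel_bank(x, k = 2, sigma = c(1, 2), normalize = "none")
  Q <- ncol(bank$kernels)
  w <- rep(1 / Q, Q)
  S <- matrix(c(0, 0.6, 0.4,
                0.5, 0, 0.5,
                0.3, 0.7, 0), 3, 3, byrow = TRUE)
  A <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
  gamma <- 1.3; beta <- 0.7; entropy <- 0.9
  # longhand evaluation
  t1 <- 0
  for (q in seq_len(Q)) t1 <- t1 - w[q] * sum(get_kernel(bank, q) * S)
  t2 <- gamma * sum(diag(t(A) %*% (diag(3) - S) %*% A))
  t3 <- entropy * sum(w * log(w))
  t4 <- beta * sum(S^2)
  expect_equal(cimlr_objective(S, A, w, bank, gamma, beta, entropy),
               t1 + t2 + t3 + t4)
  # closed forms: S with all entries 1/N has unit squared Frobenius
  # norm; uniform w gives mu*log(1/Q)
  Su <- matrix(1 / 3, 3, 3)
  expect_equal(beta * sum(Su^2), beta)
  expect_equal(entropy * sum(w * log(w)), entropy * log(1 / Q))
})

test_that("shape mismatches in the objective are rejected", {
  x <- minmax_scale(matrix(runif(12), 4, 3))
  bank <- kernel_bank(x, k = 2, sigma = 1)
  expect_error(cimlr_objective(diag(3), diag(4)[, 1:2],
                               rep(1 / 3, 3), bank, 1, 1, 1), "S")
  expect_error(cimlr_objective(diag(4), diag(4)[, 1:2],
                               rep(1, 5), bank, 1, 1, 1), "weight")
})

test_that("the S-step row solution is the constrained minimiser", {
  # exhaustive check on a fine simplex grid (N = 3: two free
  # off-diagonal coordinates per row)
  set.seed(8)
  G <- matrix(rnorm(9, sd = 2), 3, 3)
  S <- markerclust:::.project_rows_simplex(G)
  expect_equal(diag(S), rep(0, 3))
  expect_equal(rowSums(S), rep(1, 3))
  for (i in 1:3) {
    free <- setdiff(1:3, i)
    best <- Inf
    for (g1 in seq(0, 1, by = 0.002)) {
      val <- sum((c(g1, 1 - g1) - G[i, free])^2)
      if (val < best) best <- val
    }
    expect_lte(sum((S[i, free] - G[i, free])^2), best + 1e-6)
  }
  # random feasible points never beat the projection (N = 8)
  G8 <- matrix(rnorm(64), 8, 8)
  S8 <- markerclust:::.project_rows_simplex(G8)
  set.seed(9)
  for (i in 1:8) {
    free <- setdiff(1:8, i)
    f_star <- sum((S8[i, free] - G8[i, free])^2)
    for (r in 1:200) {
      cand <- rexp(7)
      cand <- cand / sum(cand)
      expect_gte(sum((cand - G8[i, free])^2), f_star - 1e-12)
    }
  }
})

test_that("fitting is equivariant under subject permutation", {
  coh <- small_cohort(n_subjects = 60, n_markers = 15, n_clusters = 3,
                      seed = 21)
  fit1 <- fit_small(coh)
  set.seed(33)
  perm <- sample(nrow(coh$markers))
  fit2 <- cimlr(coh$markers[perm, ], clusters = 3, embed = FALSE,
                seed = 1)
  expect_equal(unname(fit2$S), unname(fit1$S[perm, perm]),
               tolerance = 1e-8)
  expect_equal(ari(fit2$labels, fit1$labels[perm]), 1)
})

test_that("labels are reproducible for a fixed seed", {
  coh <- small_cohort(n_subjects = 50, n_markers = 15, n_clusters = 2,
                      seed = 2)
  f1 <- cimlr(coh$markers, clusters = 2, seed = 7)
  f2 <- cimlr(coh$markers, clusters = 2, seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("structureless data still converges cleanly", {
  coh <- small_cohort(marker_shift = 0, seed = 13)
  fit <- fit_small(coh)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$objective)))
})

test_that("planted clusters are recovered through the embedding path", {
  coh <- small_cohort(seed = 11, n_subjects = 120, n_markers = 30)
  fit <- cimlr(coh$markers, clusters = 4, seed = 1)
  expect_gte(ari(fit$labels, coh$true_cluster), 0.9)
  # informative-column k-means achieves the same recovery (oracle)
  km <- kmeans(minmax_scale(coh$markers)[, coh$informative_markers],
               4, nstart = 30)
  expect_gte(ari(km$cluster, coh$true_cluster), 0.9)
})

test_that("argument validation catches impossible cluster counts", {
  coh <- small_cohort(n_subjects = 20, n_markers = 8, n_clusters = 2,
                      seed = 1)
  expect_error(cimlr(coh$markers, clusters = 1), "at least 2")
  expect_error(cimlr(coh$markers, clusters = 11), "subjects")
})

test_that("print, summary, coef and plot methods work", {
  coh <- small_cohort(n_subjects = 50, n_markers = 12, n_clusters = 2,
                      seed = 2)
  fit <- cimlr(coh$markers, clusters = 2, seed = 3)
  expect_output(print(fit), "converged")
  expect_output(print(summary(fit, top = 3)), "Top markers")
  expect_length(coef(fit), 12)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_length(coef(fit, "kernels"), 12 * 15)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
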