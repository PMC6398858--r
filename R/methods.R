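#' @export
print.cimlr <- function(x, ...) {
  cat("Multi-kernel similarity clustering\n")
  cat(sprintf("  %d subjects, %d markers, %d kernels; C = %d\n",
              length(x$subject_ids), length(x$marker_ids),
              length(x$w), x$clusters))
  cat(sprintf("  %s after %d iterations (objective %.6g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, utils::tail(x$objective, 1)))
  if (!is.null(x$labels))
    cat("  cluster sizes: ",
        paste(tabulate(x$labels, x$clusters), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Summarise a fitted similarity-clustering model
#'
#' Reports convergence, cluster sizes, and the top markers by aggregated
#' kernel weight (see [marker_importance()]).
#'
#' @param object A `"cimlr"` fit.
#' @param top Number of top markers to show.
#' @param ... Unused.
#' @export
summary.cimlr <- function(object, top = 10, ...) {
  imp <- marker_importance(object)
  out <- list(fit = object, importance = utils::head(imp, top))
  class(out) <- "summary.cimlr"
  out
}

#' @export
print.summary.cimlr <- function(x, ...) {
  print(x$fit)
  cat("\nTop markers by kernel weight:\n")
  print(x$importance, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract kernel weights or marker importances
#'
#' @param object A `"cimlr"` fit.
#' @param type `"markers"` (default) aggregates the weights of each
#'   marker's kernels into a single importance; `"kernels"` returns the
#'   raw per-kernel weight vector.
#' @param ... Unused.
#' @return A named numeric vector.
#' @export
coef.cimlr <- function(object, type = c("markers", "kernels"), ...) {
  type <- match.arg(type)
  if (type == "kernels") return(object$w)
  imp <- marker_importance(object)
  stats::setNames(imp$importance, imp$marker)
}

#' Plot a fitted similarity-clustering model
#'
#' Two base-graphics panels: the learned similarity matrix with subjects
#' ordered by cluster (block structure appears as diagonal blocks), and
#' the 2-D embedding coloured by cluster (if an embedding was computed).
#'
#' @param x A `"cimlr"` fit.
#' @param which Any of `"similarity"`, `"embedding"`.
#' @param ... Passed to [graphics::image()] / [graphics::plot()].
#' @export
plot.cimlr <- function(x, which = c("similarity", "embedding"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  ord <- order(x$labels)
  if ("similarity" %in% which) {
    M <- (x$S + t(x$S))[ord, rev(ord)] / 2
    graphics::image(M, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, main = "Learned similarity (cluster order)",
                    ...)
  }
  if ("embedding" %in% which && !is.null(x$embedding)) {
    graphics::plot(x$embedding, col = x$labels, pch = 19,
                   xlab = "dim 1", ylab = "dim 2",
                   main = "Similarity embedding", ...)
    graphics::legend("topright", legend = paste0("C", seq_len(x$clusters)),
                     col = seq_len(x$clusters), pch = 19, bty = "n")
  }
  invisible(x)
}
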