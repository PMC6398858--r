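#' Read a marker, volume or metadata CSV
#'
#' Readers for the tabular schemas written by [write_cohort()]; real
#' cohort exports with the same headers are accepted identically.
#' `read_markers()` returns a numeric subjects-by-markers matrix with
#' subject ids as row names; `read_volumes()` returns a list with the
#' region matrix and the `icv` vector; `read_metadata()` returns the
#' metadata data frame with `diagnosis` as a CN/MCI/AD factor.
#'
#' @param path Path to the CSV file.
#' @return See description.
#' @export
read_markers <- function(path) {
  df <- .read_table(path)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject_id
  m
}

#' @rdname read_markers
#' @export
read_volumes <- function(path) {
  df <- .read_table(path)
  if (!"icv" %in% names(df)) stop("no 'icv' column in ", path)
  m <- as.matrix(df[, setdiff(names(df), c("subject_id", "icv")),
                    drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject_id
  list(volumes = m, icv = stats::setNames(df$icv, df$subject_id))
}

#' @rdname read_markers
#' @export
read_metadata <- function(path) {
  df <- .read_table(path)
  if ("diagnosis" %in% names(df))
    df$diagnosis <- factor(df$diagnosis, levels = c("CN", "MCI", "AD"))
  df
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("no 'subject_id' column in ", path)
  df
}

#' Missing-value filtering of a marker table
#'
#' Applies the two-step completeness rule used to assemble a single-visit
#' analysis cohort: first drop subjects whose required metadata fields
#' (e.g. scan or marker availability) are missing, then drop every marker
#' column that still contains a missing value among the retained subjects.
#' The result is a complete-case matrix; the ids removed at each step are
#' recorded in a provenance attribute.
#'
#' @param markers Numeric matrix (subjects x markers) with subject ids as
#'   row names; may contain `NA`.
#' @param subjects Optional data frame keyed by `subject_id` with the
#'   required per-subject fields; subjects with any `NA` in
#'   `required` (default: all non-id columns) are dropped, as are marker
#'   rows without a metadata record.
#' @param required Character vector of column names of `subjects` that
#'   must be non-missing.
#' @return The filtered numeric matrix, with attribute `"provenance"`: a
#'   list with `dropped_subjects` and `dropped_markers`.
#' @examples
#' m <- matrix(c(1, 2, NA, 4, 5, 6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("m1", "m2")))
#' filter_missing(m)  # drops m1
#' @export
filter_missing <- function(markers, subjects = NULL, required = NULL) {
  stopifnot(is.matrix(markers), !is.null(rownames(markers)))
  dropped_subjects <- character(0)
  keep <- rownames(markers)
  if (!is.null(subjects)) {
    stopifnot("subject_id" %in% names(subjects))
    if (is.null(required))
      required <- setdiff(names(subjects), "subject_id")
    ok <- if (length(required) == 0L) rep(TRUE, nrow(subjects)) else
      !Reduce(`|`, lapply(subjects[required], is.na))
    valid <- subjects$subject_id[ok]
    dropped_subjects <- setdiff(keep, valid)
    keep <- intersect(keep, valid)
    if (length(keep) == 0L)
      stop("no subjects left after the subject completeness filter")
  }
  out <- markers[keep, , drop = FALSE]
  bad <- apply(out, 2, anyNA)
  dropped_markers <- colnames(out)[bad]
  out <- out[, !bad, drop = FALSE]
  if (ncol(out) == 0L)
    stop("no markers left after the marker completeness filter")
  attr(out, "provenance") <- list(dropped_subjects = dropped_subjects,
                                  dropped_markers = dropped_markers)
  out
}

#' Normalise region volumes by intracranial volume
#'
#' Divides each subject's region volumes by that subject's estimated
#' intracranial volume, removing head-size effects. The result is a
#' dimensionless positive ratio matrix.
#'
#' @param volumes Numeric matrix (subjects x regions).
#' @param icv Positive numeric vector of intracranial volumes, one per
#'   subject (matched by name when both are named, else by position).
#' @return The normalised matrix, with attribute `normalized = TRUE`.
#' @export
normalize_volumes <- function(volumes, icv) {
  stopifnot(is.matrix(volumes))
  if (!is.null(names(icv)) && !is.null(rownames(volumes))) {
    if (!all(rownames(volumes) %in% names(icv)))
      stop("icv is missing for some subjects")
    icv <- icv[rownames(volumes)]
  }
  if (length(icv) != nrow(volumes))
    stop("'icv' must have one value per subject")
  bad <- which(!is.finite(icv) | icv <= 0)
  if (length(bad))
    stop("nonpositive ICV for subject(s): ",
         paste(if (is.null(names(icv))) bad else names(icv)[bad],
               collapse = ", "))
  out <- volumes / icv
  attr(out, "normalized") <- TRUE
  out
}

#' Min-max scale each column to the unit interval
#'
#' Subtracts the per-column minimum and divides by the per-column range,
#' so every column lies in `[0, 1]` and (unless constant) attains both
#' endpoints. Constant columns are mapped to all zeros with a warning, the
#' limit of the formula as the range shrinks that also preserves zero
#' entries. Scaling parameters are computed on the data passed in (the
#' single-cohort design: no held-out reference).
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return The scaled matrix.
#' @examples
#' minmax_scale(cbind(a = c(0, 5, 10)))  # 0, 0.5, 1
#' @export
minmax_scale <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(x)[const], collapse = ", "))
    span[const] <- 1
  }
  out <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  out[, const] <- 0
  out
}
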