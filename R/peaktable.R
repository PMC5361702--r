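#' Construct a peak table
#'
#' A peak table holds a features x samples intensity matrix together with
#' per-feature metadata (m/z, retention time, optional adduct annotation).
#' Missing cells are represented by `NA` in the intensity matrix and can be
#' inspected with [is_missing()]; observed intensities must be non-negative.
#'
#' @param intensities Numeric features x samples matrix. Row names are feature
#'   ids, column names are sample ids; both must be unique. `NA` marks a
#'   missing (undetected) cell.
#' @param mz Optional numeric vector of feature m/z values (Thomson), positive.
#' @param rt Optional numeric vector of retention times (minutes),
#'   non-negative.
#' @param adduct Optional character vector of adduct annotations per feature
#'   (e.g. `"[M+H]+"`); `NA` where unannotated.
#'
#' @return An object of class `peak_table`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 3,
#'             dimnames = list(paste0("F", 1:3), c("S1", "S2")))
#' pt <- peak_table(m, mz = c(100.1, 200.2, 300.3))
#' n_features(pt)
peak_table <- function(intensities, mz = NULL, rt = NULL, adduct = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(intensities)
  sid <- colnames(intensities)
  if (is.null(fid) || is.null(sid)) {
    stop("`intensities` must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  storage.mode(intensities) <- "double"
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("observed intensities must be >= 0", call. = FALSE)
  }
  p <- nrow(intensities)
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != p) {
      stop("`", what, "` must have one value per feature", call. = FALSE)
    }
    x
  }
  mz <- check_len(mz, "mz")
  rt <- check_len(rt, "rt")
  adduct <- check_len(adduct, "adduct")
  if (!is.null(mz) && any(mz <= 0, na.rm = TRUE)) {
    stop("`mz` values must be positive", call. = FALSE)
  }
  if (!is.null(rt) && any(rt < 0, na.rm = TRUE)) {
    stop("`rt` values must be non-negative", call. = FALSE)
  }
  features <- tibble::tibble(
    feature_id = fid,
    mz = if (is.null(mz)) NA_real_ else as.numeric(mz),
    rt = if (is.null(rt)) NA_real_ else as.numeric(rt),
    adduct = if (is.null(adduct)) NA_character_ else as.character(adduct)
  )
  structure(list(values = intensities, features = features),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", n_features(x), " features x ", n_samples(x),
      " samples; ", sum(is_missing(x)), " missing cells (",
      sprintf("%.1f%%", 100 * mean(is_missing(x))), ")\n", sep = "")
  invisible(x)
}

#' Peak table accessors
#'
#' @param pt A [peak_table()].
#' @return `intensity_matrix()` the numeric matrix (NA = missing);
#'   `is_missing()` the logical missing mask; `feature_ids()` /
#'   `sample_ids()` character vectors; `feature_data()` the feature metadata
#'   tibble; `n_features()` / `n_samples()` integers.
#' @export
intensity_matrix <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  pt$values
}

#' @rdname intensity_matrix
#' @export
is_missing <- function(pt) is.na(intensity_matrix(pt))

#' @rdname intensity_matrix
#' @export
feature_ids <- function(pt) rownames(intensity_matrix(pt))

#' @rdname intensity_matrix
#' @export
sample_ids <- function(pt) colnames(intensity_matrix(pt))

#' @rdname intensity_matrix
#' @export
feature_data <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  pt$features
}

#' @rdname intensity_matrix
#' @export
n_features <- function(pt) nrow(intensity_matrix(pt))

#' @rdname intensity_matrix
#' @export
n_samples <- function(pt) ncol(intensity_matrix(pt))

# Replace the intensity matrix, keeping metadata for surviving features.
# Used internally by every transformation; `check_nonneg` is turned off for
# transformed/scaled tables which legitimately carry negative values.
set_intensities <- function(pt, values, check_nonneg = FALSE) {
  stopifnot(inherits(pt, "peak_table"), is.matrix(values))
  if (check_nonneg && any(values < 0, na.rm = TRUE)) {
    stop("observed intensities must be >= 0", call. = FALSE)
  }
  keep <- match(rownames(values), pt$features$feature_id)
  if (anyNA(keep)) stop("unknown feature ids in replacement matrix", call. = FALSE)
  pt$values <- values
  pt$features <- pt$features[keep, , drop = FALSE]
  pt
}

#' Subset a peak table
#'
#' @param x A [peak_table()].
#' @param i Feature selector (ids, indices or logical).
#' @param j Sample selector (ids, indices or logical).
#' @param ... Unused.
#' @export
`[.peak_table` <- function(x, i, j, ...) {
  m <- x$values
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  set_intensities(x, m[i, j, drop = FALSE])
}

#' Peak table as a long tibble
#'
#' @param x A [peak_table()].
#' @param ... Unused.
#' @return A tibble with one row per feature/sample cell: `feature_id`,
#'   `sample`, `intensity` (NA when missing), plus `mz`, `rt`, `adduct`.
#' @export
tidy.peak_table <- function(x, ...) {
  m <- intensity_matrix(x)
  out <- tibble::tibble(
    feature_id = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    intensity = as.vector(m)
  )
  dplyr::left_join(out, feature_data(x), by = "feature_id")
}

#' One-line summary of a peak table
#'
#' @param x A [peak_table()].
#' @param ... Unused.
#' @return A one-row tibble: feature/sample counts, missing-cell count and
#'   fraction, intensity range.
#' @export
glance.peak_table <- function(x, ...) {
  m <- intensity_matrix(x)
  tibble::tibble(
    n_features = nrow(m),
    n_samples = ncol(m),
    n_missing = sum(is.na(m)),
    frac_missing = mean(is.na(m)),
    min_intensity = suppressWarnings(min(m, na.rm = TRUE)),
    max_intensity = suppressWarnings(max(m, na.rm = TRUE))
  )
}
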