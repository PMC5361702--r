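#' Read a peak table from CSV/TSV
#'
#' Parses a wide feature x sample intensity table as exported by peak-picking
#' software. Two header dialects are supported: `generic` (first column is the
#' feature id; optional metadata columns named `mz`/`m/z`, `rt`/`retention
#' time`, `adduct`; every other column is a sample) and `progenesis_qi`
#' (metadata columns identified by the canonical Progenesis QI headers
#' `Compound`, `m/z`, `Retention time (min)` and optionally `Adducts`; all
#' remaining columns are samples).
#'
#' Empty cells and `"NA"` are always missing. Exact zeros are treated as
#' missing by default (`zero_as_missing = TRUE`), the usual exporter
#' convention for undetected peaks.
#'
#' @param path Path to a delimited text file. Delimiter inferred from the
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @param dialect `"generic"` or `"progenesis_qi"`.
#' @param sample_list Optional sample metadata (see [read_sample_list()]);
#'   when supplied, intensity columns are resolved against its sample ids and
#'   a mismatch is an error naming the offending columns.
#' @param zero_as_missing Mask exact zeros as missing? Default `TRUE`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("generic", "progenesis_qi"),
                            sample_list = NULL, zero_as_missing = TRUE) {
  dialect <- match.arg(dialect)
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0L) stop("peak table is empty: ", path, call. = FALSE)
  nm <- names(raw)

  if (dialect == "progenesis_qi") {
    id_col <- match_header(nm, "compound")
    if (is.na(id_col)) stop("Progenesis dialect requires a 'Compound' column",
                            call. = FALSE)
    mz_col <- match_header(nm, "m/z")
    rt_col <- match_header(nm, "retention time (min)")
    ad_col <- match_header(nm, "adducts")
  } else {
    id_col <- 1L
    mz_col <- match_header(nm, c("mz", "m/z"))
    rt_col <- match_header(nm, c("rt", "retention time", "retention time (min)"))
    ad_col <- match_header(nm, c("adduct", "adducts"))
  }
  meta_cols <- stats::na.omit(c(id_col, mz_col, rt_col, ad_col))

  sample_cols <- setdiff(seq_along(nm), meta_cols)
  if (!is.null(sample_list)) {
    want <- sample_list$sample
    found <- nm[sample_cols]
    extra <- setdiff(found, want)
    absent <- setdiff(want, found)
    if (length(extra) || length(absent)) {
      stop("peak-table sample columns do not match the sample list",
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")),
           if (length(absent)) paste0("; missing: ",
                                      paste(absent, collapse = ", ")),
           call. = FALSE)
    }
    sample_cols <- sample_cols[match(want, found)]  # sample-list order
  }
  if (length(sample_cols) == 0L) stop("no intensity columns found", call. = FALSE)

  fid <- as.character(raw[[id_col]])
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(raw[sample_cols], as.numeric)))
  dimnames(m) <- list(fid, nm[sample_cols])
  if (zero_as_missing) m[!is.na(m) & m == 0] <- NA_real_

  peak_table(
    m,
    mz = if (!is.na(mz_col)) as.numeric(raw[[mz_col]]),
    rt = if (!is.na(rt_col)) as.numeric(raw[[rt_col]]),
    adduct = if (!is.na(ad_col)) as.character(raw[[ad_col]])
  )
}

match_header <- function(nm, candidates) {
  hit <- which(tolower(trimws(nm)) %in% tolower(candidates))
  if (length(hit)) hit[1] else NA_integer_
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"), progress = FALSE)
}

#' Read a sample list
#'
#' Tab-delimited file with columns `sample`, `batch`, `class`, `order`.
#' A row whose `class` is empty or `"NA"` is a pooled quality-control (QC)
#' injection and gets `is_qc = TRUE`; `order` is the injection order.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `sample_meta` with columns `sample`, `batch`
#'   (character), `class` (character, `NA` for QCs), `order` (integer) and
#'   `is_qc` (logical).
#' @export
read_sample_list <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample", "batch", "class", "order")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("sample list is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_meta(sample = raw$sample, batch = raw$batch, class = raw$class,
              order = raw$order)
}

#' Construct sample metadata
#'
#' @param sample Unique sample ids.
#' @param batch Batch labels (coerced to character).
#' @param class Group labels; `NA` (or empty) marks a QC sample.
#' @param order Injection order, unique positive integers.
#' @return A tibble of class `sample_meta`.
#' @export
sample_meta <- function(sample, batch, class, order) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "),
         call. = FALSE)
  }
  class <- as.character(class)
  class[!is.na(class) & trimws(class) == ""] <- NA_character_
  order_num <- suppressWarnings(as.numeric(order))
  if (anyNA(order_num) || any(order_num != round(order_num)) ||
      any(order_num < 1)) {
    stop("`order` must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(order_num)) {
    stop("injection order values must be unique", call. = FALSE)
  }
  out <- tibble::tibble(
    sample = sample,
    batch = as.character(batch),
    class = class,
    order = as.integer(order_num),
    is_qc = is.na(class)
  )
  class(out) <- c("sample_meta", class(out))
  out
}

# Align metadata rows to a peak table's samples; errors on uncovered samples.
align_meta <- function(pt, meta) {
  idx <- match(sample_ids(pt), meta$sample)
  if (anyNA(idx)) {
    stop("sample list does not cover sample(s): ",
         paste(sample_ids(pt)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}

#' Load a compound database
#'
#' Reads a local compound table (a stand-in for HMDB/KEGG-style databases)
#' with columns `compound_id` (alias `id`), `name`, `formula` and
#' `monoisotopic_mass` (alias `mass`, in Daltons). Rows with a non-positive
#' mass are dropped with a warning; records are sorted ascending by mass so
#' that mass-window queries can binary-search.
#'
#' @param path Path to the TSV file.
#' @param source Optional source tag attached to every record (used when
#'   merging several databases).
#' @return A tibble of class `compound_db`, sorted by `monoisotopic_mass`.
#' @export
load_compound_db <- function(path, source = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  names(raw) <- nm
  if ("id" %in% nm && !"compound_id" %in% nm) {
    names(raw)[nm == "id"] <- "compound_id"
  }
  if ("mass" %in% nm && !"monoisotopic_mass" %in% nm) {
    names(raw)[names(raw) == "mass"] <- "monoisotopic_mass"
  }
  need <- c("compound_id", "name", "formula", "monoisotopic_mass")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("compound database is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  db <- tibble::as_tibble(raw[need])
  db$compound_id <- as.character(db$compound_id)
  db$monoisotopic_mass <- as.numeric(db$monoisotopic_mass)
  bad <- is.na(db$monoisotopic_mass) | db$monoisotopic_mass <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive mass rejected",
            call. = FALSE)
    db <- db[!bad, , drop = FALSE]
  }
  if (anyDuplicated(db$compound_id)) {
    stop("duplicate compound ids", call. = FALSE)
  }
  db <- db[order(db$monoisotopic_mass), , drop = FALSE]
  if (!is.null(source)) db$source <- source
  class(db) <- c("compound_db", class(db))
  db
}

#' Merge compound databases
#'
#' Concatenates several databases (keeping their `source` tags) and re-sorts
#' by mass.
#'
#' @param ... `compound_db` tibbles from [load_compound_db()].
#' @return A merged `compound_db`.
#' @export
merge_compound_dbs <- function(...) {
  dbs <- list(...)
  stopifnot(length(dbs) > 0)
  out <- dplyr::bind_rows(lapply(dbs, function(d) {
    if (!"source" %in% names(d)) d$source <- NA_character_
    tibble::as_tibble(unclass(d))
  }))
  out <- out[order(out$monoisotopic_mass), , drop = FALSE]
  class(out) <- c("compound_db", class(out))
  out
}

# Binary-search retrieval of database rows with mass in [lo, hi].
db_mass_window <- function(db, lo, hi) {
  mass <- db$monoisotopic_mass
  i <- findInterval(lo, mass, left.open = TRUE) + 1L
  j <- findInterval(hi, mass)
  if (i > j) return(db[0, , drop = FALSE])
  db[i:j, , drop = FALSE]
}

#' Write a tabular result to CSV/TSV
#'
#' @param table A data frame (any analysis result).
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_table <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!is.data.frame(table)) table <- as.data.frame(table)
  if (ncol(table) == 0L) stop("cannot write a table with no columns", call. = FALSE)
  if (format == "csv") readr::write_csv(table, path, progress = FALSE)
  else readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Write a peak table to CSV/TSV
#'
#' Writes feature id, m/z, RT and adduct columns followed by one intensity
#' column per sample; missing cells are written empty. Reading the file back
#' with [read_peak_table()] (with `zero_as_missing = FALSE`) reproduces the
#' matrix and missing mask exactly.
#'
#' @param pt A [peak_table()].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_peak_table <- function(pt, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  fd <- feature_data(pt)
  out <- data.frame(feature = fd$feature_id, mz = fd$mz, rt = fd$rt,
                    adduct = fd$adduct, check.names = FALSE)
  out <- cbind(out, as.data.frame(intensity_matrix(pt), check.names = FALSE))
  write_table(out, path, format)
}
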