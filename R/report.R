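#' Generate a self-contained HTML report
#'
#' Assembles the supplied stage results into a single HTML document with no
#' external assets: quality-assessment series, normalization comparison,
#' univariate excerpt, multivariate summaries (R2Y/Q2Y/permutation p),
#' network summary, identification table and biomarker evaluation — one
#' section per executed stage, in pipeline order — plus a provenance block
#' (package version, seed, configuration, input content hashes). Output is
#' deterministic given identical inputs: no timestamps enter the document.
#'
#' @param results A named list; recognised elements are `qa`
#'   ([qa_summary()]), `normalization` ([compare_normalizations()]),
#'   `univariate` ([univariate_tests()]), `multivariate` (a list of
#'   `multivariate_model`s), `permutation` ([permutation_test()]),
#'   `network` (a `correlation_graph`), `identification`
#'   ([match_features()]), `biomarker` ([rfe_select()]), `evaluation`
#'   ([evaluate_model()]), `power` ([estimate_power()]).
#' @param path Output HTML path.
#' @param config Optional named list echoed into the provenance block.
#' @param seed Optional seed echoed into the provenance block.
#' @param max_rows Row cap for embedded tables. Default 50.
#' @return The path, invisibly.
#' @export
generate_report <- function(results, path, config = list(), seed = NULL,
                            max_rows = 50) {
  known <- c("qa", "normalization", "univariate", "multivariate",
             "permutation", "network", "identification", "biomarker",
             "evaluation", "power")
  results <- results[intersect(names(results), known)]
  if (length(results) == 0) {
    stop("no stage results to report", call. = FALSE)
  }
  sections <- character(0)
  add <- function(title, body) {
    sections <<- c(sections,
                   paste0("<section><h2>", html_escape(title), "</h2>\n",
                          body, "\n</section>"))
  }
  if (!is.null(results$qa)) {
    qa <- results$qa
    add("Per-sample quality series", html_table(qa$samples, max_rows))
    add("Missing-value distribution",
        html_table(qa$samples[, c("sample", "detected", "missing")], max_rows))
    add("Total intensity by injection order",
        html_table(qa$samples[, c("sample", "order", "total_intensity")],
                   max_rows))
    add("Feature m/z and retention time", html_table(qa$features, max_rows))
    if (!is.null(qa$qc_correlation)) {
      add("QC sample correlation",
          html_table(tibble::as_tibble(round(qa$qc_correlation, 4),
                                       rownames = "sample"), max_rows))
    }
    add("PCA scores", html_table(qa$pca_scores, max_rows))
  }
  if (!is.null(results$normalization)) {
    add("Normalization comparison", html_table(results$normalization, max_rows))
  }
  if (!is.null(results$univariate)) {
    uni <- results$univariate
    uni <- uni[order(uni$q), , drop = FALSE]
    add("Univariate statistics (top features)", html_table(uni, max_rows))
  }
  if (!is.null(results$multivariate)) {
    mv <- results$multivariate
    if (inherits(mv, "multivariate_model")) mv <- list(mv)
    add("Multivariate models",
        html_table(dplyr::bind_rows(lapply(mv, glance)), max_rows))
  }
  if (!is.null(results$permutation)) {
    pr <- results$permutation
    add("Permutation test",
        html_table(tibble::tibble(model = pr$model_kind,
                                  q2y_observed = pr$q2y_observed,
                                  n_perm = pr$n_perm,
                                  p_value = pr$p_value), max_rows))
  }
  if (!is.null(results$network)) {
    add("Correlation network", html_table(glance(results$network), max_rows))
  }
  if (!is.null(results$identification)) {
    add("Metabolite identification", html_table(results$identification,
                                                max_rows))
  }
  if (!is.null(results$biomarker)) {
    add("Biomarker selection (RFE profile)",
        html_table(tidy(results$biomarker), max_rows))
  }
  if (!is.null(results$evaluation)) {
    add("Biomarker evaluation", html_table(glance(results$evaluation),
                                           max_rows))
  }
  if (!is.null(results$power)) {
    add("Power analysis", html_table(results$power, max_rows))
  }
  prov <- tibble::tibble(
    key = c("package", "version",
            if (!is.null(seed)) "seed",
            names(config),
            "content_hash"),
    value = c("metapeak", as.character(utils::packageVersion("metapeak")),
              if (!is.null(seed)) as.character(seed),
              vapply(config, function(v) paste(format(v), collapse = ","),
                     character(1)),
              content_hash(results))
  )
  add("Provenance", html_table(prov, Inf))
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>metapeak report</title>\n<style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #ccc;padding:2px 8px;font-size:90%}",
    "h1{border-bottom:2px solid #444}",
    "</style></head>\n<body>\n<h1>metapeak analysis report</h1>\n",
    paste(sections, collapse = "\n"), "\n</body></html>\n")
  writeLines(html, path, sep = "")
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows) {
  df <- as.data.frame(df)
  truncated <- nrow(df) > max_rows
  if (truncated) df <- df[seq_len(max_rows), , drop = FALSE]
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 6, format = "g") else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(cells, 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""),
           "</tr>")
  })
  paste0("<table>", head, paste(rows, collapse = ""), "</table>",
         if (truncated) paste0("<p>(first ", max_rows, " rows shown)</p>"))
}

# Deterministic content hash of the reportable results (no timestamps):
# serialize with a fixed version and fold into a polynomial hex digest.
content_hash <- function(results) {
  raw <- serialize(results, NULL, version = 2)
  idx <- seq(1, length(raw), by = max(1, length(raw) %/% 4096))
  h <- 5381
  for (b in as.integer(raw[idx])) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x%08x", h, length(raw) %% 2147483647)
}
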