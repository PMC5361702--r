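# Shared fixture builders: everything is generated in code.

# Peak table from a plain matrix (auto feature/sample names).
tiny_pt <- function(values, mz = NULL, rt = NULL, adduct = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  peak_table(values, mz = mz, rt = rt, adduct = adduct)
}

# Sample metadata for n experimental samples (+ optional QCs appended).
tiny_meta <- function(classes, batch = "1", n_qc = 0) {
  n <- length(classes) + n_qc
  sample_meta(
    sample = c(paste0("S", seq_along(classes)),
               if (n_qc > 0) paste0("QC", seq_len(n_qc))),
    batch = rep(batch, length.out = n),
    class = c(classes, rep(NA_character_, n_qc)),
    order = seq_len(n)
  )
}

# Two 4-cliques joined by a single bridge edge (modularity fixture).
two_clique_edges <- function() {
  cl <- function(prefix) {
    pairs <- utils::combn(paste0(prefix, 1:4), 2)
    data.frame(from = pairs[1, ], to = pairs[2, ])
  }
  rbind(cl("a"), cl("b"), data.frame(from = "a1", to = "b1"))
}

# Direct modularity formula Q = sum_c (e_c/m - (d_c/2m)^2).
modularity_direct <- function(edges, membership) {
  m <- nrow(edges)
  comms <- unique(membership)
  sum(vapply(comms, function(c) {
    nodes <- names(membership)[membership == c]
    e_c <- sum(edges$from %in% nodes & edges$to %in% nodes)
    d_c <- sum(edges$from %in% nodes) + sum(edges$to %in% nodes)
    e_c / m - (d_c / (2 * m))^2
  }, numeric(1)))
}

# Small compound database written to a temp TSV; returns the path.
write_tiny_db <- function(masses, ids = NULL) {
  n <- length(masses)
  ids <- ids %||% paste0("C", seq_len(n))
  path <- tempfile("db", fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    compound_id = ids, name = paste0("compound_", ids),
    formula = rep("CHNOPS", n), monoisotopic_mass = masses), path)
  path
}

# Pair of vectors with exact sample correlation r (Gram-Schmidt).
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  xs <- as.numeric(scale(x))
  es <- as.numeric(scale(e))
  y <- r * xs + sqrt(1 - r^2) * es
  list(x = xs, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
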