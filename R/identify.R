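#' Built-in adduct rules
#'
#' Mass shifts (Da) use the electron-corrected proton/sodium/potassium/
#' ammonium masses to five decimals: `[M+H]+` +1.00728, `[M+Na]+` +22.98922,
#' `[M+K]+` +38.96316, `[M+NH4]+` +18.03383, `[M-H]-` -1.00728.
#' The neutral monoisotopic mass of a singly charged ion is
#' `M = mz * charge - mass_shift`.
#'
#' @param names Optional subset of adduct names to return.
#' @param polarity Optional filter, `"positive"` or `"negative"`.
#' @return A tibble of class `adduct_rules`: `name`, `mass_shift`, `charge`,
#'   `polarity`.
#' @export
adduct_rules <- function(names = NULL, polarity = NULL) {
  rules <- tibble::tibble(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M-H]-"),
    mass_shift = c(1.00728, 22.98922, 38.96316, 18.03383, -1.00728),
    charge = c(1L, 1L, 1L, 1L, 1L),
    polarity = c("positive", "positive", "positive", "positive", "negative")
  )
  if (!is.null(polarity)) {
    rules <- rules[rules$polarity %in% polarity, , drop = FALSE]
  }
  if (!is.null(names)) {
    miss <- setdiff(names, rules$name)
    if (length(miss)) stop("unknown adduct(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    rules <- rules[match(names, rules$name), , drop = FALSE]
  }
  rules
}

#' Infer a neutral monoisotopic mass from an observed m/z
#'
#' `M = mz * charge - mass_shift` for the given adduct rule.
#'
#' @param mz Observed m/z (Thomson), positive.
#' @param adduct A single adduct name (see [adduct_rules()]) or a one-row
#'   rules tibble.
#' @return The inferred neutral mass in Daltons.
#' @export
#' @examples
#' infer_neutral_mass(100.00728, "[M+H]+")   # 99
infer_neutral_mass <- function(mz, adduct) {
  rule <- if (is.character(adduct)) adduct_rules(names = adduct) else adduct
  stopifnot(nrow(rule) == 1)
  m <- mz * rule$charge - rule$mass_shift
  if (any(m <= 0)) stop("inferred neutral mass is non-positive", call. = FALSE)
  m
}

#' Match peak-table features against a compound database
#'
#' For each feature with an m/z, infers candidate neutral masses under the
#' supplied adduct rules and retrieves (by binary search over the
#' mass-sorted database) every compound whose monoisotopic mass lies within
#' `tol_ppm` parts per million:
#' `delta_ppm = (inferred - db_mass) / db_mass * 1e6` (observed heavier
#' than the database gives a positive delta). When `use_annotations = TRUE`
#' and a feature carries an adduct annotation, only that adduct is tried
#' (features annotated as isotope peaks, e.g. `"[M+1]+"`, are skipped);
#' otherwise all supplied adducts are tried.
#'
#' @param pt A [peak_table()] whose features carry `mz` values.
#' @param db A [load_compound_db()] table.
#' @param tol_ppm Match tolerance in ppm. Default 10.
#' @param adducts An [adduct_rules()] tibble (non-empty).
#' @param use_annotations Honour per-feature adduct annotations. Default
#'   `TRUE`.
#' @return A tibble of hits sorted per feature by `abs(delta_ppm)`:
#'   `feature_id`, `mz`, `adduct`, `inferred_neutral_mass`, `compound_id`,
#'   `name`, `formula`, `db_mass`, `delta_ppm`.
#' @export
match_features <- function(pt, db, tol_ppm = 10,
                           adducts = adduct_rules(polarity = "positive"),
                           use_annotations = TRUE) {
  if (is.null(adducts) || nrow(adducts) == 0) {
    stop("adduct rule list is empty", call. = FALSE)
  }
  fd <- feature_data(pt)
  hits <- purrr::map_dfr(seq_len(nrow(fd)), function(i) {
    mz <- fd$mz[i]
    if (is.na(mz)) return(NULL)
    ann <- fd$adduct[i]
    rules <- adducts
    if (use_annotations && !is.na(ann) && nzchar(ann)) {
      if (grepl("\\[M\\+[0-9]", ann)) return(NULL)  # isotope peak
      if (ann %in% adducts$name) {
        rules <- adducts[adducts$name == ann, , drop = FALSE]
      }
    }
    purrr::map_dfr(seq_len(nrow(rules)), function(r) {
      rule <- rules[r, , drop = FALSE]
      neutral <- mz * rule$charge - rule$mass_shift
      if (neutral <= 0) return(NULL)
      lo <- neutral / (1 + tol_ppm * 1e-6)
      hi <- neutral / (1 - tol_ppm * 1e-6)
      cand <- db_mass_window(db, lo, hi)
      if (nrow(cand) == 0) return(NULL)
      delta <- (neutral - cand$monoisotopic_mass) /
        cand$monoisotopic_mass * 1e6
      keep <- abs(delta) <= tol_ppm
      if (!any(keep)) return(NULL)
      tibble::tibble(
        feature_id = fd$feature_id[i], mz = mz, adduct = rule$name,
        inferred_neutral_mass = neutral,
        compound_id = cand$compound_id[keep], name = cand$name[keep],
        formula = cand$formula[keep], db_mass = cand$monoisotopic_mass[keep],
        delta_ppm = delta[keep])
    })
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      feature_id = character(), mz = numeric(), adduct = character(),
      inferred_neutral_mass = numeric(), compound_id = character(),
      name = character(), formula = character(), db_mass = numeric(),
      delta_ppm = numeric()))
  }
  hits[order(match(hits$feature_id, fd$feature_id), abs(hits$delta_ppm)), ,
       drop = FALSE]
}
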