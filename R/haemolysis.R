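#' Haemolysis detection settings
#'
#' The delta-Cq rule compares a plasma-enriched miRNA (default miR-23a-3p)
#' with a red-blood-cell-enriched miRNA (default miR-451a): haemolysis
#' releases miR-451a into plasma, lowering its Cq and inflating
#' `Cq(plasma marker) - Cq(RBC marker)`. Samples with a difference strictly
#' above the threshold (default 7 cycles) are called contaminated; a
#' difference strictly below is clear; equality raises a boundary warning
#' without flagging.
#'
#' @param dcq_threshold Cq-difference cut-off, must be > 0.
#' @param plasma_marker,rbc_marker assay ids of the marker pair
#'   (miR-16-5p is a commonly used alternate RBC comparator).
#' @return a `haemolysis_settings` list.
#' @export
haemolysis_settings <- function(dcq_threshold = 7,
                                plasma_marker = "hsa-miR-23a-3p",
                                rbc_marker = "hsa-miR-451a") {
  if (!is.numeric(dcq_threshold) || dcq_threshold <= 0) {
    .stopf("dcq_threshold must be > 0")
  }
  structure(list(dcq_threshold = dcq_threshold,
                 plasma_marker = plasma_marker,
                 rbc_marker = rbc_marker),
            class = "haemolysis_settings")
}

#' Delta-Cq haemolysis call per sample
#'
#' @param cq a [cq_table()] containing both marker assays.
#' @param settings a [haemolysis_settings()].
#' @return data.frame with one row per sample: `dcq_score` (Cq units),
#'   `dcq_flag` (contaminated), `boundary_warning` (score equals the
#'   threshold exactly), `evaluable` (both markers measured).
#' @export
dcq_haemolysis <- function(cq, settings = haemolysis_settings()) {
  stopifnot(inherits(cq, "cq_table"))
  for (m in c(settings$plasma_marker, settings$rbc_marker)) {
    if (!m %in% colnames(cq)) .stopf("marker assay absent from Cq table: %s", m)
  }
  score <- cq[, settings$plasma_marker] - cq[, settings$rbc_marker]
  evaluable <- !is.na(score)
  flag <- !is.na(score) & score > settings$dcq_threshold
  boundary <- !is.na(score) & score == settings$dcq_threshold
  data.frame(sample_id = rownames(cq),
             dcq_score = as.numeric(score),
             dcq_flag = flag,
             boundary_warning = boundary,
             evaluable = evaluable,
             row.names = NULL)
}

#' Read absorbance spectra
#'
#' Long format `sample_id,wavelength_nm,absorbance`; per sample, wavelengths
#' must be strictly increasing (rows may arrive unsorted and are sorted).
#'
#' @param path delimited text file.
#' @param sep optional explicit delimiter.
#' @return data.frame of class `spectra_table`.
#' @export
read_spectra <- function(path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  need <- c("sample_id", "wavelength_nm", "absorbance")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    .stopf("spectra file is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df <- df[order(df$sample_id, df$wavelength_nm), need]
  rownames(df) <- NULL
  dup <- tapply(df$wavelength_nm, df$sample_id, anyDuplicated)
  if (any(dup > 0)) .stopf("duplicated wavelengths for sample %s", names(dup)[dup > 0][1L])
  class(df) <- c("spectra_table", "data.frame")
  df
}

# linearly interpolated absorbance at `wl` for one sample's (sorted) spectrum
.spectrum_at <- function(wavelengths, absorbance, wl) {
  if (any(wl < min(wavelengths) | wl > max(wavelengths))) {
    .stopf("wavelength(s) %s outside the measured range [%g, %g] nm",
           paste(wl[wl < min(wavelengths) | wl > max(wavelengths)], collapse = ", "),
           min(wavelengths), max(wavelengths))
  }
  stats::approx(wavelengths, absorbance, xout = wl, method = "linear")$y
}

#' Named absorbance wavelength schemes
#'
#' `shkurnikov` (primary 415 nm, references 450 and 700 nm) and `kahn`
#' (primary 578 nm, references 562 and 598 nm) are the two published
#' three-wavelength haemoglobin schemes; `peak414` is raw absorbance at the
#' oxyhaemoglobin Soret peak, 414 nm.
#'
#' @return a named list of presets (`primary`, `refs` in nm).
#' @export
absorbance_presets <- function() {
  list(shkurnikov = list(primary = 415, refs = c(450, 700)),
       kahn = list(primary = 578, refs = c(562, 598)),
       peak414 = list(primary = 414, refs = numeric(0)))
}

#' Absorbance-based haemolysis score
#'
#' For the named three-wavelength presets the score is the baseline-corrected
#' peak height: `A(primary) - L(primary)`, where `L` is the straight line
#' through the two reference wavelengths. This reproduces the structure of
#' published haemoglobin scores while leaving their exact coefficients to a
#' user-supplied map: pass a named numeric vector `wavelength -> weight` to
#' compute `sum(w * A(lambda))` instead. `peak414` is raw `A(414)`.
#'
#' Baseline-corrected scores are invariant to adding a constant to the whole
#' spectrum and scale linearly when the spectrum is scaled.
#'
#' @param spectra a [read_spectra()] table (or any data.frame with
#'   `sample_id`, `wavelength_nm`, `absorbance`).
#' @param method a preset name (see [absorbance_presets()]) or a named
#'   numeric coefficient vector.
#' @return data.frame `sample_id`, `method`, `score` (OD units).
#' @export
absorbance_haemolysis <- function(spectra, method = "shkurnikov") {
  stopifnot(is.data.frame(spectra))
  if (is.numeric(method)) {
    if (length(method) == 0L) .stopf("empty coefficient map")
    if (is.null(names(method))) .stopf("coefficient map must be named by wavelength")
    wls <- as.numeric(names(method))
    score_one <- function(w, a) sum(method * .spectrum_at(w, a, wls))
    label <- "custom"
  } else {
    presets <- absorbance_presets()
    if (!method %in% names(presets)) {
      .stopf("unknown preset %s (known: %s)", deparse(method),
             paste(names(presets), collapse = ", "))
    }
    p <- presets[[method]]
    label <- method
    score_one <- function(w, a) {
      ap <- .spectrum_at(w, a, p$primary)
      if (length(p$refs) == 0L) return(ap)
      ar <- .spectrum_at(w, a, p$refs)
      # linear baseline through the two reference points, evaluated at the peak
      slope <- (ar[2L] - ar[1L]) / (p$refs[2L] - p$refs[1L])
      ap - (ar[1L] + slope * (p$primary - p$refs[1L]))
    }
  }
  ids <- unique(spectra$sample_id)
  scores <- vapply(ids, function(s) {
    rows <- spectra$sample_id == s
    score_one(spectra$wavelength_nm[rows], spectra$absorbance[rows])
  }, numeric(1))
  data.frame(sample_id = ids, method = label, score = as.numeric(scores),
             row.names = NULL)
}

#' Combined haemolysis report
#'
#' Runs the delta-Cq rule and any number of absorbance presets, returning one
#' row per sample with one score column per method.
#'
#' @param cq a [cq_table()].
#' @param spectra optional [read_spectra()] table.
#' @param settings a [haemolysis_settings()].
#' @param presets absorbance preset names to compute when spectra are given.
#' @return wide data.frame; delta-Cq columns as in [dcq_haemolysis()], plus
#'   one column per absorbance method.
#' @export
haemolysis_report <- function(cq, spectra = NULL,
                              settings = haemolysis_settings(),
                              presets = c("shkurnikov", "kahn", "peak414")) {
  rep <- dcq_haemolysis(cq, settings)
  if (!is.null(spectra)) {
    for (p in presets) {
      sc <- absorbance_haemolysis(spectra, p)
      rep[[p]] <- sc$score[match(rep$sample_id, sc$sample_id)]
    }
  }
  rep
}

#' Concordance between haemolysis scoring methods
#'
#' For each score column, Pearson correlation and least-squares line against
#' a reference score (default the raw 414 nm absorbance), mirroring the usual
#' per-method scatter-plot comparison. Pairs with fewer than 3 complete
#' observations or zero variance are reported as not evaluable with a reason.
#'
#' @param scores wide data.frame with `sample_id` and one numeric column per
#'   method (e.g. output of [haemolysis_report()]).
#' @param reference name of the reference score column.
#' @param methods columns to compare; default all numeric columns except the
#'   reference and the delta-Cq bookkeeping columns.
#' @return data.frame `method`, `n`, `r`, `slope`, `intercept`, `evaluable`,
#'   `reason`.
#' @export
method_concordance <- function(scores, reference = "peak414", methods = NULL) {
  if (!reference %in% colnames(scores)) .stopf("reference column %s absent", reference)
  if (is.null(methods)) {
    numeric_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
    methods <- setdiff(numeric_cols, c(reference, "dcq_flag", "boundary_warning", "evaluable"))
  }
  x <- scores[[reference]]
  out <- lapply(methods, function(m) {
    y <- scores[[m]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) {
      return(data.frame(method = m, n = n, r = NA_real_, slope = NA_real_,
                        intercept = NA_real_, evaluable = FALSE,
                        reason = "fewer than 3 paired observations"))
    }
    xi <- x[ok]; yi <- y[ok]
    if (stats::var(xi) == 0 || stats::var(yi) == 0) {
      return(data.frame(method = m, n = n, r = NA_real_, slope = NA_real_,
                        intercept = NA_real_, evaluable = FALSE,
                        reason = "zero variance"))
    }
    r <- stats::cor(xi, yi)
    slope <- stats::cov(xi, yi) / stats::var(xi)
    data.frame(method = m, n = n, r = r, slope = slope,
               intercept = mean(yi) - slope * mean(xi),
               evaluable = TRUE, reason = "")
  })
  do.call(rbind, out)
}
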