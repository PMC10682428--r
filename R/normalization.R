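#' Sex-stratified age adjustment of Cq values
#'
#' Within each sex stratum, each assay's Cq is regressed on age by ordinary
#' least squares and replaced by `residual + stratum assay mean`. This removes
#' the linear age trend while preserving the Cq scale and each stratum's
#' location, so downstream thresholds keep their meaning. Strata with fewer
#' than 3 complete samples, or with constant age, are passed through
#' unchanged with a warning (a slope cannot be estimated there).
#'
#' @param cq a [cq_table()].
#' @param meta metadata with `sample_id`, `sex`, `age` for every sample.
#' @return list: `$cq` the adjusted [cq_table()]; `$model` a data.frame with
#'   one row per (sex, assay): `intercept`, `slope`, `stratum_mean`, `n`.
#' @export
age_sex_adjust <- function(cq, meta) {
  stopifnot(inherits(cq, "cq_table"))
  need <- c("sample_id", "sex", "age")
  missing_cols <- setdiff(need, colnames(meta))
  if (length(missing_cols)) .stopf("metadata lacks: %s", paste(missing_cols, collapse = ", "))
  m <- meta[match(rownames(cq), meta$sample_id), ]
  if (any(is.na(m$sample_id))) .stopf("metadata missing for some Cq samples")
  if (any(is.na(m$age)) || any(is.na(m$sex) | m$sex == "")) {
    .stopf("age and sex must be available for all samples")
  }
  out <- unclass(cq)
  rows <- list()
  for (sx in unique(m$sex)) {
    idx <- which(m$sex == sx)
    ages <- m$age[idx]
    degenerate <- length(idx) < 3L || stats::var(ages) == 0
    if (degenerate) {
      .warnf("sex stratum %s: %s; Cq passed through unadjusted",
             sx, if (length(idx) < 3L) "fewer than 3 samples" else "constant age")
    }
    for (a in colnames(cq)) {
      v <- out[idx, a]
      ok <- !is.na(v)
      mu <- mean(v[ok])
      if (degenerate || sum(ok) < 3L || stats::var(ages[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, assay_id = a, intercept = mu, slope = 0,
          stratum_mean = mu, n = sum(ok))
        next
      }
      fit <- stats::lm.fit(cbind(1, ages[ok]), v[ok])
      out[idx[ok], a] <- fit$residuals + mu
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, assay_id = a, intercept = fit$coefficients[1L],
        slope = fit$coefficients[2L], stratum_mean = mu, n = sum(ok))
    }
  }
  list(cq = cq_table(out, permissive = TRUE), model = do.call(rbind, rows))
}

#' Per-sample reference Cq of a normalizer combination
#'
#' The arithmetic mean of the member assays' Cq — on the log2 Cq scale this
#' is the geometric mean of the members' relative quantities, the standard
#' multi-reference normalization factor. A sample missing any member's Cq
#' gets a missing reference and is excluded downstream.
#'
#' @param cq a [cq_table()].
#' @param combination non-empty character vector of member assay ids.
#' @return named numeric vector, one reference Cq per sample.
#' @export
reference_mean <- function(cq, combination) {
  stopifnot(inherits(cq, "cq_table"))
  combination <- as.character(combination)
  if (length(combination) == 0L) .stopf("empty combination")
  absent <- setdiff(combination, colnames(cq))
  if (length(absent)) .stopf("combination assay(s) absent: %s", paste(absent, collapse = ", "))
  rowMeans(unclass(cq)[, combination, drop = FALSE])  # NA propagates
}

#' Relative expression as -ddCq
#'
#' The normalization engine behind every stability computation. Per sample
#' `s`: `dCq_s = Cq(target, s) - reference_mean(s)`; `ddCq_s = dCq_s - m`
#' where `m` is the mean `dCq` over control-group samples
#' (`reference_mode = "control_group_mean"`, standard ddCq usage) or over all
#' samples (`"grand_mean"`); the returned value is `-ddCq_s`, identically
#' `log2(2^-ddCq_s)` — log2 relative expression under perfect doubling.
#'
#' Consequences worth knowing: under control-group referencing the control
#' group's mean value is exactly 0 for every target; a target normalized
#' against itself alone is identically 0; adding a constant to a sample's
#' target and all member Cq leaves the value unchanged.
#'
#' @param cq a [cq_table()].
#' @param target target assay id.
#' @param combination normalizer combination (may include the target).
#' @param groups named character vector `sample_id -> group label` covering
#'   all samples of `cq`.
#' @param control_label group label acting as the reference group.
#' @param reference_mode `"control_group_mean"` or `"grand_mean"`.
#' @return data.frame of class `normalized_values`: `sample_id`, `group`,
#'   `value` (-ddCq, NA where any needed Cq is missing), with the call's
#'   target/combination/mode stored as attributes.
#' @export
neg_ddcq <- function(cq, target, combination, groups, control_label,
                     reference_mode = c("control_group_mean", "grand_mean")) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(inherits(cq, "cq_table"))
  if (!target %in% colnames(cq)) .stopf("target assay absent: %s", target)
  ref <- reference_mean(cq, combination)
  grp <- groups[rownames(cq)]
  if (any(is.na(grp))) .stopf("group label missing for sample(s): %s",
                              paste(rownames(cq)[is.na(grp)], collapse = ", "))
  dcq <- unclass(cq)[, target] - ref
  if (reference_mode == "control_group_mean") {
    ctrl <- dcq[grp == control_label]
    if (!any(!is.na(ctrl))) .stopf("no control-group sample has complete data for target %s", target)
    m <- mean(ctrl, na.rm = TRUE)
  } else {
    m <- mean(dcq, na.rm = TRUE)
  }
  structure(data.frame(sample_id = rownames(cq), group = as.character(grp),
                       value = as.numeric(-(dcq - m)), row.names = NULL),
            class = c("normalized_values", "data.frame"),
            target = target, combination = as.character(combination),
            reference_mode = reference_mode)
}
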