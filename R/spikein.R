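#' Spike-in control configuration
#'
#' Exogenous C. elegans miRNAs added at a fixed amount monitor the efficiency
#' of two wet-lab stages: miRNA isolation (spiked before extraction) and
#' reverse transcription (spiked before cDNA synthesis). A sample whose
#' spike-in Cq deviates strongly from the rest of its stratum indicates a
#' stage failure for that sample.
#'
#' @param isolation,rt assay ids per stage.
#' @param z_threshold flag a stage when any of its spike-ins has `|z|` above
#'   this (a conservative ANY rule: single spike-ins can fail idiosyncratically).
#' @param grouping metadata columns defining the strata within which z-scores
#'   are computed. Default `"cohort"`: flagging is a technical call and should
#'   not depend on diagnosis.
#' @return a `spikein_config` list.
#' @export
spikein_config <- function(isolation = c("cel-miR-39-3p", "cel-miR-2-3p"),
                           rt = c("cel-miR-238-3p", "cel-miR-54-3p"),
                           z_threshold = 2,
                           grouping = "cohort") {
  if (!is.numeric(z_threshold) || z_threshold <= 0) .stopf("z_threshold must be > 0")
  structure(list(isolation = as.character(isolation), rt = as.character(rt),
                 z_threshold = z_threshold, grouping = grouping),
            class = "spikein_config")
}

# stratum label per sample from the grouping columns (all samples in one
# stratum when no grouping column is available)
.spike_strata <- function(meta, ids, grouping) {
  cols <- intersect(grouping, colnames(meta))
  if (length(cols) == 0L) return(stats::setNames(rep("all", length(ids)), ids))
  m <- meta[match(ids, meta$sample_id), cols, drop = FALSE]
  stats::setNames(do.call(paste, c(m, sep = "/")), ids)
}

#' Spike-in z-scores and stage outlier flags
#'
#' Within each stratum and spike-in assay, `z = (Cq - stratum mean) /
#' stratum sample SD`. A stage is flagged for a sample when any of that
#' stage's spike-ins exceeds the threshold in absolute value. Strata with
#' fewer than 3 samples, or with zero SD, yield undefined z-scores with an
#' explanatory reason, never a flag.
#'
#' @param cq a [cq_table()] containing the configured spike-in assays.
#' @param meta sample metadata (used for stratification only).
#' @param config a [spikein_config()].
#' @return list of class `spikein_report`: `$zscores` (long, one row per
#'   sample x spike-in: `cq`, `z`, `stage`, `reason`), `$samples` (per sample:
#'   `isolation_outlier`, `rt_outlier`, per-stage mean deviation from the
#'   stratum median, in Cq units).
#' @export
spikein_zscores <- function(cq, meta, config = spikein_config()) {
  stopifnot(inherits(cq, "cq_table"))
  assays <- c(config$isolation, config$rt)
  stage <- c(rep("isolation", length(config$isolation)), rep("rt", length(config$rt)))
  absent <- setdiff(assays, colnames(cq))
  if (length(absent)) .stopf("spike-in assay(s) absent from Cq table: %s",
                             paste(absent, collapse = ", "))
  ids <- rownames(cq)
  strata <- .spike_strata(meta, ids, config$grouping)

  long <- do.call(rbind, lapply(seq_along(assays), function(k) {
    a <- assays[k]
    v <- cq[, a]
    z <- rep(NA_real_, length(v))
    reason <- rep("", length(v))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      vv <- v[idx]
      n_obs <- sum(!is.na(vv))
      if (n_obs < 3L) {
        reason[idx] <- "stratum has fewer than 3 samples"
      } else if (.sd_or_na(vv) == 0) {
        reason[idx] <- "zero SD in stratum"
      } else {
        z[idx] <- (vv - mean(vv, na.rm = TRUE)) / stats::sd(vv[!is.na(vv)])
      }
    }
    reason[is.na(v) & reason == ""] <- "missing Cq"
    data.frame(sample_id = ids, assay_id = a, stage = stage[k],
               stratum = as.character(strata), cq = as.numeric(v),
               z = z, reason = reason, row.names = NULL)
  }))

  flag_stage <- function(st) {
    zz <- long[long$stage == st, ]
    tapply(abs(zz$z) > config$z_threshold, zz$sample_id,
           function(f) any(f, na.rm = TRUE))[ids]
  }
  dev_stage <- function(st) {
    zz <- long[long$stage == st, ]
    dev <- stats::ave(zz$cq, zz$assay_id, zz$stratum,
                      FUN = function(v) v - stats::median(v, na.rm = TRUE))
    tapply(dev, zz$sample_id, function(d) mean(d, na.rm = TRUE))[ids]
  }
  samples <- data.frame(sample_id = ids,
                        isolation_outlier = as.logical(flag_stage("isolation")),
                        rt_outlier = as.logical(flag_stage("rt")),
                        isolation_deviation = as.numeric(dev_stage("isolation")),
                        rt_deviation = as.numeric(dev_stage("rt")),
                        row.names = NULL)
  structure(list(zscores = long, samples = samples, config = config),
            class = "spikein_report")
}

#' @export
print.spikein_report <- function(x, ...) {
  cat(sprintf("<spikein_report> %d samples; isolation outliers: %d, RT outliers: %d\n",
              nrow(x$samples), sum(x$samples$isolation_outlier, na.rm = TRUE),
              sum(x$samples$rt_outlier, na.rm = TRUE)))
  invisible(x)
}

#' Spike-in based Cq correction
#'
#' Report-only by default (`mode = "none"`): the recommendation to correct
#' for isolation/RT efficiency does not come with a canonical formula, so
#' data are never silently altered. With `mode = "subtract_stage_deviation"`,
#' each sample's deviation `d_s` is the mean over all configured spike-ins of
#' `Cq(spike, s) - median over samples of Cq(spike)` (median: robust to the
#' very outliers the controls exist to find), and every non-spike-in assay
#' gets `Cq - d_s`. Samples missing any spike-in Cq are left uncorrected
#' with a warning. Spike-in columns pass through unmodified unless
#' `drop_spikeins = TRUE`.
#'
#' @param cq a [cq_table()].
#' @param config a [spikein_config()].
#' @param mode `"none"` or `"subtract_stage_deviation"`.
#' @param drop_spikeins remove spike-in columns from the output.
#' @return a corrected [cq_table()].
#' @export
spikein_correction <- function(cq, config = spikein_config(),
                               mode = c("none", "subtract_stage_deviation"),
                               drop_spikeins = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cq, "cq_table"))
  if (mode == "none") return(cq)
  spikes <- c(config$isolation, config$rt)
  absent <- setdiff(spikes, colnames(cq))
  if (length(absent)) .stopf("spike-in assay(s) absent from Cq table: %s",
                             paste(absent, collapse = ", "))
  sp <- unclass(cq)[, spikes, drop = FALSE]
  dev <- sweep(sp, 2L, apply(sp, 2L, stats::median, na.rm = TRUE))
  d_s <- rowMeans(dev)
  uncorrectable <- is.na(d_s)
  if (any(uncorrectable)) {
    .warnf("%d sample(s) missing spike-in Cq left uncorrected: %s",
           sum(uncorrectable), paste(rownames(cq)[uncorrectable], collapse = ", "))
    d_s[uncorrectable] <- 0
  }
  out <- unclass(cq)
  targets <- setdiff(colnames(cq), spikes)
  out[, targets] <- out[, targets, drop = FALSE] - d_s
  if (drop_spikeins) out <- out[, targets, drop = FALSE]
  cq_table(out, permissive = TRUE)
}
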