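#' Simulation specification for a synthetic two-group plasma cohort
#'
#' Describes a case/control aging cohort of the kind the workflow targets:
#' two diagnostic groups (default 40 samples each, healthy controls vs
#' Alzheimer's disease), a panel of candidate normalizers with per-candidate
#' baseline Cq, case-group shift and within-group SD, age and sex covariate
#' effects, exogenous spike-ins with planted stage outliers, and a fraction
#' of haemolysed samples whose contamination level lowers the miR-451a Cq
#' and raises the oxyhaemoglobin absorbance bands of the paired spectra.
#'
#' Cq noise is Gaussian: Cq is a log2-scale quantity, where multiplicative
#' expression noise is approximately additive. Ground truth is written into
#' the metadata as `gt_*` columns so tests never re-derive it.
#'
#' @param n_per_group samples per group.
#' @param groups two labels, control first.
#' @param candidates data.frame `assay_id`, `baseline` (Cq), `shift` (Cq
#'   added in the case group), `sd` (within-group SD); default: the seven
#'   commonly used endogenous plasma controls, no shifts, SD 0.3.
#' @param age_range uniform age range in years.
#' @param age_slope Cq change per year, recycled over candidates.
#' @param sex_effect Cq added for male samples, recycled over candidates.
#' @param spikeins data.frame `assay_id`, `stage` (`"isolation"`/`"rt"`),
#'   `baseline`, `sd`.
#' @param spikein_outlier_frac fraction of samples with a planted spike-in
#'   failure per stage; `spikein_outlier_shift` Cq added for those samples.
#' @param haemolysis list: `fraction` of contaminated samples, `level_range`
#'   of the contamination level (arbitrary units), `rbc_baseline`/`rbc_sd`
#'   for miR-451a, `cq_drop_per_level` (Cq removed from miR-451a per unit
#'   level), `detect_level` (declared bound above which the delta-Cq rule is
#'   expected to flag).
#' @param spectra list: `noise_sd` (OD), `soret_height` (OD per unit level
#'   at 414 nm), `step` (nm grid).
#' @param seed RNG seed; a fixed seed makes all generated outputs identical.
#' @return a validated `sim_spec` list.
#' @export
sim_spec <- function(n_per_group = 40,
                     groups = c("HC", "AD"),
                     candidates = data.frame(
                       assay_id = c("hsa-miR-93-5p", "hsa-miR-192-5p",
                                    "hsa-miR-24-3p", "hsa-miR-126-3p",
                                    "hsa-miR-16-5p", "hsa-miR-484",
                                    "hsa-miR-23a-3p"),
                       baseline = c(23.5, 26.0, 24.0, 26.5, 22.0, 27.0, 25.0),
                       shift = 0,
                       sd = 0.3),
                     age_range = c(55, 85),
                     age_slope = 0,
                     sex_effect = 0,
                     spikeins = data.frame(
                       assay_id = c("cel-miR-39-3p", "cel-miR-2-3p",
                                    "cel-miR-238-3p", "cel-miR-54-3p"),
                       stage = c("isolation", "isolation", "rt", "rt"),
                       baseline = c(20.0, 21.0, 19.5, 20.5),
                       sd = 0.25),
                     spikein_outlier_frac = 0.02,
                     spikein_outlier_shift = 3,
                     haemolysis = list(fraction = 0.1,
                                       level_range = c(0.2, 2.0),
                                       rbc_baseline = 22.0, rbc_sd = 0.4,
                                       cq_drop_per_level = 5,
                                       detect_level = 1.3),
                     spectra = list(noise_sd = 0.005, soret_height = 0.9,
                                    step = 1),
                     seed = 1) {
  chk <- function(cond, field) if (!cond) .stopf("invalid sim_spec field: %s", field)
  chk(is.numeric(n_per_group) && n_per_group >= 1, "n_per_group")
  chk(length(groups) == 2L && !anyDuplicated(groups), "groups")
  chk(is.data.frame(candidates) &&
        all(c("assay_id", "baseline", "shift", "sd") %in% colnames(candidates)) &&
        nrow(candidates) >= 1L && !anyDuplicated(candidates$assay_id),
      "candidates")
  chk(all(candidates$sd >= 0), "candidates$sd")
  chk(length(age_range) == 2L && age_range[1L] <= age_range[2L] &&
        all(age_range >= 0), "age_range")
  chk(is.data.frame(spikeins) &&
        all(c("assay_id", "stage", "baseline", "sd") %in% colnames(spikeins)) &&
        all(spikeins$stage %in% c("isolation", "rt")) && all(spikeins$sd >= 0),
      "spikeins")
  chk(spikein_outlier_frac >= 0 && spikein_outlier_frac <= 1, "spikein_outlier_frac")
  chk(haemolysis$fraction >= 0 && haemolysis$fraction <= 1, "haemolysis$fraction")
  chk(haemolysis$rbc_sd >= 0, "haemolysis$rbc_sd")
  chk(spectra$noise_sd >= 0, "spectra$noise_sd")
  chk(is.numeric(seed) && length(seed) == 1L, "seed")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 candidates = candidates, age_range = age_range,
                 age_slope = rep_len(age_slope, nrow(candidates)),
                 sex_effect = rep_len(sex_effect, nrow(candidates)),
                 spikeins = spikeins,
                 spikein_outlier_frac = spikein_outlier_frac,
                 spikein_outlier_shift = spikein_outlier_shift,
                 haemolysis = haemolysis, spectra = spectra,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a Cq dataset
#'
#' Generates `Cq(sample, assay) = baseline + shift * [case] +
#' age_slope * (age - mean age) + sex_effect * [male] + N(0, sd)` for the
#' candidate panel, spike-in columns with planted per-stage outliers, and a
#' miR-451a column whose Cq drops by `cq_drop_per_level` per unit of planted
#' contamination. Metadata carries `gt_contamination_level`,
#' `gt_is_contaminated` and `gt_spikein_outlier` ground-truth columns.
#'
#' @param spec a [sim_spec()].
#' @return a `mirnorm_dataset` (see [assemble_dataset()]).
#' @export
simulate_cq_dataset <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- 2L * spec$n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(spec$groups, each = spec$n_per_group)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::runif(n, spec$age_range[1L], spec$age_range[2L])

  n_contam <- round(spec$haemolysis$fraction * n)
  contam_idx <- if (n_contam > 0) sample(n, n_contam) else integer(0)
  level <- numeric(n)
  if (n_contam > 0) {
    level[contam_idx] <- stats::runif(n_contam, spec$haemolysis$level_range[1L],
                                      spec$haemolysis$level_range[2L])
  }

  cand <- spec$candidates
  # draw per-assay noise in alphabetical assay order so the generated values
  # do not depend on how the candidate panel happens to be ordered
  draw_order <- order(cand$assay_id)
  cqm <- sapply(draw_order, function(j) {
    cand$baseline[j] + cand$shift[j] * (group == spec$groups[2L]) +
      spec$age_slope[j] * (age - mean(age)) +
      spec$sex_effect[j] * (sex == "M") +
      stats::rnorm(n, 0, cand$sd[j])
  })
  colnames(cqm) <- cand$assay_id[draw_order]
  cqm <- cqm[, cand$assay_id, drop = FALSE]

  rbc <- spec$haemolysis$rbc_baseline + stats::rnorm(n, 0, spec$haemolysis$rbc_sd) -
    spec$haemolysis$cq_drop_per_level * level
  cqm <- cbind(cqm, "hsa-miR-451a" = rbc)

  sp <- spec$spikeins
  n_out <- round(spec$spikein_outlier_frac * n)
  outlier <- list(isolation = if (n_out > 0) sample(n, n_out) else integer(0),
                  rt = if (n_out > 0) sample(n, n_out) else integer(0))
  sp_order <- order(sp$assay_id)
  spm <- sapply(sp_order, function(j) {
    v <- sp$baseline[j] + stats::rnorm(n, 0, sp$sd[j])
    v[outlier[[sp$stage[j]]]] <- v[outlier[[sp$stage[j]]]] + spec$spikein_outlier_shift
    v
  })
  colnames(spm) <- sp$assay_id[sp_order]
  spm <- spm[, sp$assay_id, drop = FALSE]
  cqm <- cbind(cqm, spm)
  rownames(cqm) <- ids

  meta <- data.frame(sample_id = ids, group = group, sex = sex, age = age,
                     batch = "run1", cohort = "sim",
                     gt_contamination_level = level,
                     gt_is_contaminated = level > 0,
                     gt_spikein_outlier = seq_len(n) %in%
                       unique(c(outlier$isolation, outlier$rt)))
  panel <- panel_config(candidates = cand$assay_id,
                        spikein_isolation = sp$assay_id[sp$stage == "isolation"],
                        spikein_rt = sp$assay_id[sp$stage == "rt"])
  structure(list(cq = cq_table(cqm, permissive = TRUE), meta = meta,
                 panel = panel),
            class = "mirnorm_dataset")
}

#' Simulate absorbance spectra
#'
#' Per sample over 220-750 nm: a smooth plasma baseline (protein band near
#' 280 nm) plus the contamination level times a haemoglobin signature —
#' a Soret band at 414 nm and secondary oxyhaemoglobin bands at 541 and
#' 577 nm, all modelled as Gaussians (a structural stand-in, not measured
#' extinction curves) — plus Gaussian OD noise. When `dataset` is given, the
#' spectra reuse its sample ids and planted contamination levels; otherwise
#' a standalone cohort with its own levels is generated.
#'
#' @param spec a [sim_spec()].
#' @param dataset optional paired output of [simulate_cq_dataset()].
#' @return a `spectra_table` data.frame (`sample_id`, `wavelength_nm`,
#'   `absorbance`).
#' @export
simulate_spectra <- function(spec = sim_spec(), dataset = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1000L)
  if (!is.null(dataset)) {
    ids <- dataset$meta$sample_id
    level <- dataset$meta$gt_contamination_level
  } else {
    n <- 2L * spec$n_per_group
    ids <- sprintf("S%03d", seq_len(n))
    n_contam <- round(spec$haemolysis$fraction * n)
    level <- numeric(n)
    if (n_contam > 0) {
      idx <- sample(n, n_contam)
      level[idx] <- stats::runif(n_contam, spec$haemolysis$level_range[1L],
                                 spec$haemolysis$level_range[2L])
    }
  }
  wl <- seq(220, 750, by = spec$spectra$step)
  baseline <- 0.05 + 0.6 * exp(-((wl - 280) / 40)^2)
  hb <- spec$spectra$soret_height * exp(-((wl - 414) / 20)^2) +
    0.22 * exp(-((wl - 541) / 12)^2) + 0.25 * exp(-((wl - 577) / 12)^2)
  out <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(sample_id = ids[i], wavelength_nm = wl,
               absorbance = baseline + level[i] * hb +
                 stats::rnorm(length(wl), 0, spec$spectra$noise_sd))
  }))
  rownames(out) <- NULL
  class(out) <- c("spectra_table", "data.frame")
  out
}
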