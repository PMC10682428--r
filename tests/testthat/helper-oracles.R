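# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (explicit loops, stats::ks.test, pairwise counting)
# and shares no code with the package's scoring path.

toy_cq <- function(values, samples = NULL, assays = NULL) {
  values <- as.matrix(values)
  if (is.null(samples)) {
    samples <- if (is.null(rownames(values))) paste0("S", seq_len(nrow(values)))
               else rownames(values)
  }
  if (is.null(assays)) {
    assays <- if (is.null(colnames(values))) paste0("A", seq_len(ncol(values)))
              else colnames(values)
  }
  cq_table(values, samples, assays, permissive = TRUE)
}

# tiny two-group dataset around a candidate panel
toy_dataset <- function(values, groups, candidates = colnames(values)) {
  cq <- toy_cq(values, assays = colnames(values))
  meta <- data.frame(sample_id = rownames(cq), group = groups,
                     sex = rep(c("F", "M"), length.out = nrow(cq)),
                     age = seq(60, 80, length.out = nrow(cq)),
                     cohort = "toy")
  panel <- panel_config(candidates,
                        haemolysis_plasma_marker = candidates[1],
                        haemolysis_rbc_marker = candidates[1])
  structure(list(cq = cq, meta = meta, panel = panel),
            class = "mirnorm_dataset")
}

# brute-force combination scoring: loops over subsets (via utils::combn),
# samples and targets; KS via stats::ks.test
brute_score_all <- function(dataset, control, case, min_group_n = 3) {
  cand <- dataset$panel$candidates
  cqm <- unclass(dataset$cq)
  grp <- setNames(as.character(dataset$meta$group), dataset$meta$sample_id)
  grp <- grp[rownames(cqm)]
  rows <- list()
  for (size in seq_along(cand)) {
    for (members in utils::combn(cand, size, simplify = FALSE)) {
      code <- sum(2^(match(members, cand) - 1))
      ks <- dev <- sdv <- c()
      for (target in cand) {
        ref <- apply(cqm[, members, drop = FALSE], 1,
                     function(row) sum(row) / length(row))
        dcq <- cqm[, target] - ref
        ctrl_mean <- mean(dcq[grp == control], na.rm = TRUE)
        val <- -(dcq - ctrl_mean)
        vc <- val[grp == control]; vc <- vc[!is.na(vc)]
        va <- val[grp == case]; va <- va[!is.na(va)]
        if (length(vc) < min_group_n || length(va) < min_group_n) next
        D <- if (all(vc == 0) && all(va == 0)) 0 else
          suppressWarnings(unname(stats::ks.test(vc, va)$statistic))
        ks <- c(ks, D)
        dev <- c(dev, (abs(mean(vc)) + abs(mean(va))) / 2)
        sdv <- c(sdv, (sd(vc) + sd(va)) / 2)
      }
      rows[[length(rows) + 1]] <- data.frame(
        code = code,
        ks_metric = if (length(ks)) mean(ks) else NA_real_,
        dev_metric = if (length(dev)) mean(dev) else NA_real_,
        sd_metric = if (length(sdv)) mean(sdv) else NA_real_,
        status = if (length(ks)) "ok" else "unevaluable")
    }
  }
  do.call(rbind, rows)
}

# independent rank points: strictly-worse count plus half the tie count
brute_points <- function(metric) {
  sapply(seq_along(metric), function(j) {
    sum(metric[-j] > metric[j]) + sum(metric[-j] == metric[j]) / 2
  })
}

brute_rank <- function(scores, weights = c(1, 1, 1)) {
  total <- weights[1] * brute_points(scores$ks_metric) +
    weights[2] * brute_points(scores$dev_metric) +
    weights[3] * brute_points(scores$sd_metric)
  ord <- order(-total, scores$ks_metric, scores$sd_metric, scores$code)
  scores$code[ord]
}

# panel with a planted stable subset and uniformly shifted remainder
planted_panel <- function(n_total, n_stable, shift = 1.5, sd = 0.2) {
  data.frame(
    assay_id = c(paste0("Stab", seq_len(n_stable)),
                 paste0("Un", seq_len(n_total - n_stable))),
    baseline = seq(22, 28, length.out = n_total),
    shift = c(rep(0, n_stable), rep(shift, n_total - n_stable)),
    sd = sd)
}

# fraction of seeds for which the top-ranked combination avoids every
# candidate with a planted group shift
recovery_fraction <- function(seeds, n_total = 7, n_stable = 5, shift = 1.5,
                              n_per_group = 40, sd = 0.2) {
  cand <- planted_panel(n_total, n_stable, shift, sd)
  shifted <- cand$assay_id[cand$shift > 0]
  hits <- vapply(seeds, function(s) {
    ds <- simulate_cq_dataset(sim_spec(n_per_group = n_per_group,
                                       candidates = cand, seed = s))
    res <- run_bestmirnorm(ds, "HC", "AD")
    top <- combination_members(res$rank_table$code[1], ds$panel$candidates)
    !any(top %in% shifted)
  }, logical(1))
  mean(hits)
}
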