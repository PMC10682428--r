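#' Enumerate all non-empty normalizer combinations
#'
#' For a panel of `n` candidates there are `2^n - 1` non-empty subsets. Each
#' combination gets an integer code — the bitmask over the declared panel
#' order, `code = sum(2^i)` over 0-based member indices — so codes cover
#' `1 .. 2^n - 1` exactly once and the code/members translation is emitted
#' alongside every ranking.
#'
#' @param candidates ordered candidate assay ids, or a [panel_config()].
#' @param allow_large lift the 11-candidate cap.
#' @return list of class `combination_set`: `$candidates`, `$codes`,
#'   `$members` (list of character vectors, indexed by position), and
#'   `$table` (data.frame `code`, `size`, `members` with `+`-joined names).
#' @export
enumerate_combinations <- function(candidates, allow_large = FALSE) {
  if (inherits(candidates, "panel_config")) candidates <- candidates$candidates
  candidates <- as.character(candidates)
  n <- length(candidates)
  if (n == 0L) .stopf("empty candidate panel")
  if (n > 11L && !allow_large) {
    .stopf("%d candidates give %.0f combinations; set allow_large = TRUE to proceed",
           n, 2^n - 1)
  }
  codes <- seq_len(2^n - 1L)
  members <- lapply(codes, function(code) candidates[bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L])
  structure(list(candidates = candidates, codes = codes, members = members,
                 table = data.frame(
                   code = codes,
                   size = vapply(members, length, integer(1)),
                   members = vapply(members, paste, character(1), collapse = "+"))),
            class = "combination_set")
}

#' Members of a combination code
#'
#' @param code integer code(s) in `1 .. 2^n - 1`.
#' @param candidates ordered candidate panel defining the bit order.
#' @return character vector of member assay ids (a list for several codes).
#' @export
combination_members <- function(code, candidates) {
  candidates <- as.character(candidates)
  n <- length(candidates)
  one <- function(cd) {
    if (cd < 1 || cd > 2^n - 1) .stopf("code %d outside 1..%d", cd, 2^n - 1L)
    candidates[bitwAnd(cd, 2^(seq_len(n) - 1L)) > 0L]
  }
  if (length(code) == 1L) one(code) else lapply(code, one)
}

# code for a member set under the declared panel order
.combination_code <- function(members, candidates) {
  sum(2^(match(members, candidates) - 1L))
}

# shared scoring core. cqm: plain matrix; ctrl_idx/case_idx: row indices.
# Returns metrics for ONE member set over `targets`.
.score_members <- function(cqm, members, targets, ctrl_idx, case_idx,
                           min_group_n, ks_measure) {
  ref <- rowMeans(cqm[, members, drop = FALSE])
  ks <- dev <- sdm <- rep(NA_real_, length(targets))
  kept <- logical(length(targets))
  for (i in seq_along(targets)) {
    dcq <- cqm[, targets[i]] - ref
    vc <- dcq[ctrl_idx]
    va <- dcq[case_idx]
    vc <- vc[!is.na(vc)]
    va <- va[!is.na(va)]
    if (length(vc) < min_group_n || length(va) < min_group_n) next
    m <- mean(vc)                       # control-group reference
    vc <- -(vc - m)
    va <- -(va - m)
    kept[i] <- TRUE
    ks[i] <- if (ks_measure == "statistic") {
      ks_stat(vc, va)
    } else {
      1 - suppressWarnings(stats::ks.test(vc, va)$p.value)
    }
    dev[i] <- (abs(mean(vc)) + abs(mean(va))) / 2
    sdm[i] <- (stats::sd(vc) + stats::sd(va)) / 2
  }
  if (!any(kept)) {
    return(list(ks_metric = NA_real_, dev_metric = NA_real_, sd_metric = NA_real_,
                n_targets = 0L, status = "unevaluable"))
  }
  list(ks_metric = mean(ks[kept]), dev_metric = mean(dev[kept]),
       sd_metric = mean(sdm[kept]), n_targets = sum(kept), status = "ok")
}

#' Score one normalizer combination on the three stability metrics
#'
#' Every evaluation target is normalized to the combination via -ddCq
#' (control-group referencing; see [neg_ddcq()]) and the case and control
#' value sets are compared on: the two-sample Kolmogorov-Smirnov distance
#' (`ks_metric`), the mean over the two groups of the absolute group mean
#' (`dev_metric`, displacement from zero), and the mean of the two group
#' sample SDs (`sd_metric`). Combination metrics are unweighted means over
#' targets; lower is better on all three.
#'
#' By default the target set is the full candidate panel, including members
#' of the combination under test, so every combination — including the full
#' panel — is scored on the same targets. Set `exclude_self_targets = TRUE`
#' to score only on the non-members.
#'
#' @param dataset a `mirnorm_dataset` (see [assemble_dataset()]).
#' @param combination character vector of member assay ids.
#' @param control_label,case_label the two group labels to compare.
#' @param targets evaluation targets; default the panel candidates.
#' @param min_group_n minimum complete samples per group per target; targets
#'   below it are dropped (all dropped: status `"unevaluable"`).
#' @param ks_measure `"statistic"` (the D statistic, default) or `"pvalue"`
#'   (scored as `1 - p`, so lower remains better; sample-size dependent).
#' @param exclude_self_targets drop combination members from the target set.
#' @return one-row data.frame: members, `ks_metric`, `dev_metric`,
#'   `sd_metric`, `n_targets`, `n_control`, `n_case`, `status`.
#' @export
score_combination <- function(dataset, combination, control_label, case_label,
                              targets = NULL, min_group_n = 3,
                              ks_measure = c("statistic", "pvalue"),
                              exclude_self_targets = FALSE) {
  ks_measure <- match.arg(ks_measure)
  grp <- .dataset_groups(dataset)
  labels <- unique(grp)
  for (lb in c(control_label, case_label)) {
    if (!lb %in% labels) .stopf("unknown group label: %s", lb)
  }
  if (is.null(targets)) targets <- dataset$panel$candidates
  if (exclude_self_targets) targets <- setdiff(targets, combination)
  cqm <- unclass(dataset$cq)
  ctrl_idx <- which(grp[rownames(cqm)] == control_label)
  case_idx <- which(grp[rownames(cqm)] == case_label)
  sc <- .score_members(cqm, combination, targets, ctrl_idx, case_idx,
                       min_group_n, ks_measure)
  data.frame(members = paste(combination, collapse = "+"),
             ks_metric = sc$ks_metric, dev_metric = sc$dev_metric,
             sd_metric = sc$sd_metric, n_targets = sc$n_targets,
             n_control = length(ctrl_idx), n_case = length(case_idx),
             status = sc$status, row.names = NULL)
}

#' Convert combination scores to rank points and a final ranking
#'
#' Within each metric, combinations are ranked by minimizing the metric; the
#' best receives `n_combinations - 1` points and the worst 0, with ties
#' given the average of their positions' points (so each metric's points
#' always sum to `n_c (n_c - 1) / 2`). Points are multiplied by the metric
#' weights and summed; the final rank is by descending weighted total, with
#' deterministic tie-breaks on lower `ks_metric`, then lower `sd_metric`,
#' then smaller code. Multiplying all weights by the same positive constant
#' leaves the final ordering unchanged.
#'
#' @param scores data.frame with columns `code`, `ks_metric`, `dev_metric`,
#'   `sd_metric` (and optionally `status`; non-`"ok"` rows are dropped).
#' @param weights nonnegative metric weights `(ks, dev, sd)`, at least one
#'   positive; default `c(1, 1, 1)`.
#' @return the scores data.frame (evaluable rows) with added `ks_points`,
#'   `dev_points`, `sd_points`, `total`, `final_rank`, sorted by rank.
#' @export
rank_combinations <- function(scores, weights = c(1, 1, 1)) {
  if (length(weights) != 3L || any(weights < 0) || all(weights == 0)) {
    .stopf("weights must be 3 nonnegative values with at least one positive")
  }
  if (!is.null(scores$status)) scores <- scores[scores$status == "ok", , drop = FALSE]
  n_c <- nrow(scores)
  if (n_c < 2L) .stopf("need at least 2 evaluable combinations to rank")
  if (is.null(scores$code)) scores$code <- seq_len(n_c)
  points <- function(metric) {
    if (length(unique(metric)) == 1L) {
      .warnf("all combinations tie on a metric; equal points assigned")
    }
    n_c - rank(metric, ties.method = "average")
  }
  scores$ks_points <- points(scores$ks_metric)
  scores$dev_points <- points(scores$dev_metric)
  scores$sd_points <- points(scores$sd_metric)
  scores$total <- weights[1L] * scores$ks_points +
    weights[2L] * scores$dev_points + weights[3L] * scores$sd_points
  ord <- order(-scores$total, scores$ks_metric, scores$sd_metric, scores$code)
  scores <- scores[ord, , drop = FALSE]
  scores$final_rank <- seq_len(n_c)
  rownames(scores) <- NULL
  class(scores) <- c("rank_table", "data.frame")
  scores
}

# score every combination of the panel; returns the raw score table
.score_all_combinations <- function(dataset, control_label, case_label,
                                    targets = NULL, min_group_n = 3,
                                    ks_measure = "statistic",
                                    exclude_self_targets = FALSE,
                                    allow_large = FALSE) {
  combos <- enumerate_combinations(dataset$panel$candidates, allow_large = allow_large)
  grp <- .dataset_groups(dataset)
  cqm <- unclass(dataset$cq)
  ctrl_idx <- which(grp[rownames(cqm)] == control_label)
  case_idx <- which(grp[rownames(cqm)] == case_label)
  if (length(ctrl_idx) == 0L) .stopf("unknown or empty control group: %s", control_label)
  if (length(case_idx) == 0L) .stopf("unknown or empty case group: %s", case_label)
  if (is.null(targets)) targets <- dataset$panel$candidates
  rows <- lapply(seq_along(combos$codes), function(i) {
    tg <- if (exclude_self_targets) setdiff(targets, combos$members[[i]]) else targets
    if (length(tg) == 0L) {
      return(data.frame(code = combos$codes[i], ks_metric = NA_real_,
                        dev_metric = NA_real_, sd_metric = NA_real_,
                        n_targets = 0L, status = "unevaluable"))
    }
    sc <- .score_members(cqm, combos$members[[i]], tg, ctrl_idx, case_idx,
                         min_group_n, ks_measure)
    data.frame(code = combos$codes[i], ks_metric = sc$ks_metric,
               dev_metric = sc$dev_metric, sd_metric = sc$sd_metric,
               n_targets = sc$n_targets, status = sc$status)
  })
  out <- do.call(rbind, rows)
  out$size <- combos$table$size
  out$members <- combos$table$members
  out
}

#' Run the full combinatorial normalizer ranking
#'
#' End to end: optional sample exclusion and sex-stratified age adjustment,
#' enumeration of all `2^n - 1` combinations, scoring of each on the three
#' stability metrics, and weighted rank aggregation. Also emits the
#' code/members translation table and the top-k membership view (which
#' candidates appear in each of the k best combinations).
#'
#' @param dataset a `mirnorm_dataset`.
#' @param control_label,case_label the two groups compared by every metric.
#' @param weights metric weights `(ks, dev, sd)`; see [rank_combinations()].
#' @param adjust_age_sex apply [age_sex_adjust()] before scoring.
#' @param exclude_samples sample ids to drop first (e.g. haemolysed or
#'   spike-in-flagged samples from the QC reports).
#' @param top_k combinations shown in the membership matrix.
#' @inheritParams score_combination
#' @param allow_large lift the 11-candidate cap.
#' @return list of class `bestmirnorm_result`: `$rank_table`, `$code_table`,
#'   `$top_membership` (logical candidates x top-k matrix), `$config`.
#' @export
run_bestmirnorm <- function(dataset, control_label, case_label,
                            weights = c(1, 1, 1), adjust_age_sex = FALSE,
                            exclude_samples = NULL, targets = NULL,
                            min_group_n = 3,
                            ks_measure = c("statistic", "pvalue"),
                            exclude_self_targets = FALSE, top_k = 10,
                            allow_large = FALSE) {
  ks_measure <- match.arg(ks_measure)
  if (!is.null(exclude_samples) && length(exclude_samples)) {
    keep <- setdiff(rownames(dataset$cq), exclude_samples)
    dataset <- assemble_dataset(
      cq_table(unclass(dataset$cq)[keep, , drop = FALSE], permissive = TRUE),
      dataset$meta[dataset$meta$sample_id %in% keep, , drop = FALSE],
      dataset$panel, mode = "strict")
  }
  if (adjust_age_sex) dataset$cq <- age_sex_adjust(dataset$cq, dataset$meta)$cq
  scores <- .score_all_combinations(dataset, control_label, case_label,
                                    targets = targets, min_group_n = min_group_n,
                                    ks_measure = ks_measure,
                                    exclude_self_targets = exclude_self_targets,
                                    allow_large = allow_large)
  ranked <- rank_combinations(scores, weights = weights)
  combos <- enumerate_combinations(dataset$panel$candidates, allow_large = allow_large)
  k <- min(top_k, nrow(ranked))
  top_codes <- ranked$code[seq_len(k)]
  membership <- vapply(top_codes, function(cd) {
    dataset$panel$candidates %in% combination_members(cd, dataset$panel$candidates)
  }, logical(length(dataset$panel$candidates)))
  membership <- matrix(membership, nrow = length(dataset$panel$candidates),
                       dimnames = list(dataset$panel$candidates,
                                       paste0("rank", seq_len(k))))
  structure(list(rank_table = ranked, code_table = combos$table,
                 top_membership = membership,
                 config = list(control_label = control_label,
                               case_label = case_label, weights = weights,
                               adjust_age_sex = adjust_age_sex,
                               exclude_samples = exclude_samples,
                               min_group_n = min_group_n,
                               ks_measure = ks_measure,
                               exclude_self_targets = exclude_self_targets)),
            class = "bestmirnorm_result")
}

#' @export
print.bestmirnorm_result <- function(x, ...) {
  cat(sprintf("<bestmirnorm_result> %d combinations ranked (weights ks=%g dev=%g sd=%g)\n",
              nrow(x$rank_table), x$config$weights[1L], x$config$weights[2L],
              x$config$weights[3L]))
  cat("top combinations:\n")
  print(utils::head(x$rank_table[, c("final_rank", "code", "members", "ks_metric",
                                     "dev_metric", "sd_metric", "total")], 5L),
        row.names = FALSE)
  invisible(x)
}

#' Default weight grid for the sensitivity scan
#'
#' All weightings in `{1,2,3}^3` except `(2,2,2)` and `(3,3,3)`, which are
#' uniform scalings of `(1,1,1)` and therefore produce the identical ranking
#' — 25 weightings in total.
#'
#' @return data.frame with columns `w_ks`, `w_dev`, `w_sd`.
#' @export
default_weight_grid <- function() {
  g <- expand.grid(w_ks = 1:3, w_dev = 1:3, w_sd = 1:3)
  g <- g[!(g$w_ks == g$w_dev & g$w_dev == g$w_sd & g$w_ks > 1L), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Weight-sensitivity scan of the final ranking
#'
#' Scores the combinations once and re-ranks them under every weighting of
#' the grid, reporting each weighting's top-k codes and how often each
#' combination appears in a top-k across weightings — a robustness view of
#' the winning combinations.
#'
#' @param dataset a `mirnorm_dataset`.
#' @param control_label,case_label group labels.
#' @param grid data.frame of weightings (columns `w_ks`, `w_dev`, `w_sd`);
#'   default [default_weight_grid()].
#' @param top_k ranks retained per weighting.
#' @param ... passed to the scoring stage (see [run_bestmirnorm()]).
#' @return list of class `weight_grid_result`: `$top` (long data.frame:
#'   weighting, rank, code, members), `$stability` (per combination: times
#'   in top-k, number of weightings).
#' @export
weight_grid_scan <- function(dataset, control_label, case_label,
                             grid = default_weight_grid(), top_k = 10, ...) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) .stopf("empty weight grid")
  scores <- .score_all_combinations(dataset, control_label, case_label, ...)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- as.numeric(grid[i, c("w_ks", "w_dev", "w_sd")])
    rk <- rank_combinations(scores, weights = w)
    k <- min(top_k, nrow(rk))
    data.frame(weighting = paste(w, collapse = ""),
               w_ks = w[1L], w_dev = w[2L], w_sd = w[3L],
               rank = seq_len(k), code = rk$code[seq_len(k)],
               members = rk$members[seq_len(k)])
  })
  top <- do.call(rbind, rows)
  counts <- table(top$code)
  stability <- data.frame(code = as.integer(names(counts)),
                          times_in_top = as.integer(counts),
                          n_weightings = nrow(grid))
  stability$members <- vapply(stability$code, function(cd) {
    paste(combination_members(cd, dataset$panel$candidates), collapse = "+")
  }, character(1))
  stability <- stability[order(-stability$times_in_top, stability$code), ]
  rownames(stability) <- NULL
  structure(list(top = top, stability = stability, grid = grid),
            class = "weight_grid_result")
}
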