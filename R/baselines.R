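#' geNorm stability values
#'
#' For candidate `j`, `M_j` is the mean over all other candidates `k` of the
#' sample SD of the pairwise Cq difference `Cq_j - Cq_k` — under perfect
#' doubling the SD of the pairwise log2 expression ratio. Lower M means the
#' candidate co-varies with the rest of the panel. The stepwise exclusion
#' order repeatedly removes the highest-M candidate until two remain.
#'
#' @param cq a [cq_table()].
#' @param candidates candidate assay ids (>= 2).
#' @return list of class `stability_result`: `$method = "genorm"`,
#'   `$stability` (data.frame `assay_id`, `value` = M), `$exclusion_order`
#'   (assay ids, first excluded = least stable).
#' @export
genorm <- function(cq, candidates) {
  stopifnot(inherits(cq, "cq_table"))
  candidates <- as.character(candidates)
  if (length(candidates) < 2L) .stopf("geNorm needs at least 2 candidates")
  absent <- setdiff(candidates, colnames(cq))
  if (length(absent)) .stopf("candidate(s) absent: %s", paste(absent, collapse = ", "))
  x <- unclass(cq)[, candidates, drop = FALSE]
  if (nrow(x) < 3L) .stopf("geNorm needs at least 3 samples")
  m_values <- function(cols) {
    vapply(cols, function(j) {
      mean(vapply(setdiff(cols, j), function(k) .sd_or_na(x[, j] - x[, k]),
                  numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  remaining <- candidates
  exclusion <- character(0)
  while (length(remaining) > 2L) {
    m <- m_values(remaining)
    worst <- remaining[which.max(m)]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  structure(list(method = "genorm",
                 stability = data.frame(assay_id = candidates,
                                        value = unname(m_values(candidates))),
                 exclusion_order = exclusion,
                 final_pair = remaining),
            class = "stability_result")
}

#' BestKeeper descriptive stability
#'
#' Per candidate: sample SD of Cq, coefficient of variation (percent of the
#' mean Cq), and the Pearson correlation against the BestKeeper index — the
#' per-sample arithmetic mean of all candidate Cq values. The SD (lower is
#' better) is used as the candidate's stability value when ranking.
#'
#' @param cq a [cq_table()].
#' @param candidates candidate assay ids (>= 1).
#' @return list of class `stability_result`: `$stability` (data.frame
#'   `assay_id`, `value` = SD, `cv_percent`, `r`, `reason`), `$index`
#'   (named per-sample index).
#' @export
bestkeeper <- function(cq, candidates) {
  stopifnot(inherits(cq, "cq_table"))
  candidates <- as.character(candidates)
  if (length(candidates) < 1L) .stopf("BestKeeper needs at least 1 candidate")
  absent <- setdiff(candidates, colnames(cq))
  if (length(absent)) .stopf("candidate(s) absent: %s", paste(absent, collapse = ", "))
  x <- unclass(cq)[, candidates, drop = FALSE]
  if (nrow(x) < 3L) .stopf("BestKeeper needs at least 3 samples")
  index <- rowMeans(x, na.rm = TRUE)
  rows <- lapply(candidates, function(a) {
    v <- x[, a]
    s <- .sd_or_na(v)
    cv <- 100 * s / mean(v, na.rm = TRUE)
    ok <- !is.na(v) & !is.na(index)
    if (is.na(s) || s == 0 || stats::var(index[ok]) == 0) {
      data.frame(assay_id = a, value = if (is.na(s)) NA_real_ else s,
                 cv_percent = cv, r = NA_real_, reason = "zero variance")
    } else {
      data.frame(assay_id = a, value = s, cv_percent = cv,
                 r = stats::cor(v[ok], index[ok]), reason = "")
    }
  })
  structure(list(method = "bestkeeper", stability = do.call(rbind, rows),
                 index = index),
            class = "stability_result")
}

#' NormFinder model-based stability
#'
#' Sample-centered variance-decomposition estimator: each sample's Cq is
#' centered on its mean across candidates (removing global per-sample
#' effects), then per candidate and group the deviation of the group mean
#' from the candidate's overall mean (intergroup bias) and the within-group
#' variance are estimated. The stability value is the mean over groups of
#' `|bias| + sqrt(variance / n_g)`; lower is more stable. This is the simple
#' uncorrected estimator — no small-sample shrinkage of the bias term.
#'
#' With a single group the measure falls back to the SD of the centered
#' values (no bias term), with a warning.
#'
#' @param cq a [cq_table()].
#' @param candidates candidate assay ids (>= 3 for a meaningful
#'   decomposition; fewer is an error).
#' @param groups named character vector `sample_id -> group label`.
#' @return list of class `stability_result`: `$stability` (data.frame
#'   `assay_id`, `value`, `bias`, `variance`).
#' @export
normfinder <- function(cq, candidates, groups) {
  stopifnot(inherits(cq, "cq_table"))
  candidates <- as.character(candidates)
  if (length(candidates) < 3L) .stopf("NormFinder needs at least 3 candidates")
  absent <- setdiff(candidates, colnames(cq))
  if (length(absent)) .stopf("candidate(s) absent: %s", paste(absent, collapse = ", "))
  x <- unclass(cq)[, candidates, drop = FALSE]
  grp <- as.character(groups[rownames(x)])
  if (any(is.na(grp))) .stopf("group label missing for sample(s): %s",
                              paste(rownames(x)[is.na(grp)], collapse = ", "))
  z <- x - rowMeans(x, na.rm = TRUE)   # remove per-sample global effects
  labels <- unique(grp)
  single_group <- length(labels) < 2L
  if (single_group) {
    .warnf("single group: NormFinder falls back to SD of sample-centered values")
    rows <- lapply(candidates, function(a) {
      data.frame(assay_id = a, value = .sd_or_na(z[, a]),
                 bias = NA_real_, variance = stats::var(z[, a], na.rm = TRUE))
    })
  } else {
    small <- labels[vapply(labels, function(g) sum(grp == g), integer(1)) < 2L]
    if (length(small)) .stopf("group(s) with fewer than 2 samples: %s",
                              paste(small, collapse = ", "))
    rows <- lapply(candidates, function(a) {
      overall <- mean(z[, a], na.rm = TRUE)
      per_group <- vapply(labels, function(g) {
        v <- z[grp == g, a]
        v <- v[!is.na(v)]
        d <- mean(v) - overall
        vv <- if (length(v) >= 2L) stats::var(v) else NA_real_
        c(abs(d) + sqrt(vv / length(v)), d, vv)
      }, numeric(3))
      data.frame(assay_id = a, value = mean(per_group[1L, ]),
                 bias = mean(abs(per_group[2L, ])),
                 variance = mean(per_group[3L, ]))
    })
  }
  structure(list(method = "normfinder", stability = do.call(rbind, rows)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s\n", x$method))
  print(x$stability[order(x$stability$value), ], row.names = FALSE)
  invisible(x)
}

# per-candidate stability values (lower = more stable) for one method
.candidate_stability <- function(method, cq, candidates, groups) {
  res <- switch(method,
    genorm = genorm(cq, candidates),
    bestkeeper = bestkeeper(cq, candidates),
    normfinder = normfinder(cq, candidates, groups),
    .stopf("unknown method: %s", method))
  stats::setNames(res$stability$value, res$stability$assay_id)[candidates]
}

#' Cross-method ranking of size-k normalizer combinations
#'
#' Every size-`k` subset of the candidate panel is ranked by each requested
#' method. The single-candidate algorithms (geNorm, BestKeeper SD,
#' NormFinder) score a combination as the mean of its members' stability
#' values; the combinatorial method scores combinations natively by its
#' weighted rank total. An aggregated ranking — the mean of the per-method
#' ranks — and pairwise Spearman rank correlations between methods complete
#' the comparison.
#'
#' @param dataset a `mirnorm_dataset`.
#' @param control_label,case_label group labels (used by NormFinder and the
#'   combinatorial method).
#' @param k combination size (<= panel size).
#' @param top rows shown in the top-combination table.
#' @param methods any of `"genorm"`, `"bestkeeper"`, `"normfinder"`,
#'   `"bestmirnorm"`.
#' @param weights weights for the combinatorial method.
#' @return list of class `method_comparison`: `$rankings` (one row per
#'   size-k combination: per-method rank columns and `aggregate_rank`),
#'   `$top` (each method's top `top` codes), `$spearman` (pairwise rank
#'   correlation matrix).
#' @export
aggregate_and_compare <- function(dataset, control_label, case_label, k = 3,
                                  top = 10,
                                  methods = c("genorm", "bestkeeper",
                                              "normfinder", "bestmirnorm"),
                                  weights = c(1, 1, 1)) {
  candidates <- dataset$panel$candidates
  if (k > length(candidates)) .stopf("k = %d exceeds the %d-candidate panel",
                                     k, length(candidates))
  methods <- match.arg(methods, several.ok = TRUE)
  groups <- .dataset_groups(dataset)
  sets <- utils::combn(candidates, k, simplify = FALSE)
  codes <- vapply(sets, .combination_code, numeric(1), candidates = candidates)
  out <- data.frame(code = as.integer(codes),
                    members = vapply(sets, paste, character(1), collapse = "+"))

  for (m in setdiff(methods, "bestmirnorm")) {
    stab <- .candidate_stability(m, dataset$cq, candidates, groups)
    score <- vapply(sets, function(s) mean(stab[s]), numeric(1))
    out[[paste0(m, "_rank")]] <- rank(score, ties.method = "first")
  }
  if ("bestmirnorm" %in% methods) {
    scores <- .score_all_combinations(dataset, control_label, case_label)
    ranked <- rank_combinations(scores, weights = weights)
    pos <- match(out$code, ranked$code)
    if (any(is.na(pos))) .stopf("some size-%d combinations were unevaluable", k)
    out$bestmirnorm_rank <- rank(ranked$final_rank[pos], ties.method = "first")
  }
  rank_cols <- grep("_rank$", colnames(out), value = TRUE)
  out$aggregate_rank <- rank(rowMeans(out[, rank_cols, drop = FALSE]),
                             ties.method = "first")
  out <- out[order(out$aggregate_rank), ]
  rownames(out) <- NULL

  top_n <- min(top, nrow(out))
  top_tbl <- do.call(rbind, lapply(c(rank_cols, "aggregate_rank"), function(cl) {
    ord <- order(out[[cl]])[seq_len(top_n)]
    data.frame(method = sub("_rank$", "", cl), rank = seq_len(top_n),
               code = out$code[ord], members = out$members[ord])
  }))
  spearman <- stats::cor(out[, c(rank_cols, "aggregate_rank"), drop = FALSE],
                         method = "spearman")
  dimnames(spearman) <- lapply(dimnames(spearman), sub,
                               pattern = "_rank$", replacement = "")
  structure(list(rankings = out, top = top_tbl, spearman = spearman, k = k),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d size-%d combinations\n", nrow(x$rankings), x$k))
  print(utils::head(x$rankings, 5L), row.names = FALSE)
  cat("Spearman rank correlations:\n")
  print(round(x$spearman, 3L))
  invisible(x)
}
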