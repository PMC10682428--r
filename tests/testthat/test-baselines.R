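test_that("geNorm: constant-ratio pairs score M = 0 and noise is excluded first", {
  # two candidates whose difference is constant across samples
  base <- c(24, 25, 23, 26, 24.5)
  cq <- toy_cq(cbind(A = base, B = base + 1.5))
  g <- genorm(cq, c("A", "B"))
  expect_equal(g$stability$value, c(0, 0))

  # third candidate with independent noise has strictly the largest M
  set.seed(21)
  noisy <- rnorm(5, 24, 1)
  cq3 <- toy_cq(cbind(A = base, B = base + 1.5, C = noisy))
  g3 <- genorm(cq3, c("A", "B", "C"))
  expect_equal(g3$stability$assay_id[which.max(g3$stability$value)], "C")
  expect_equal(g3$exclusion_order[1], "C")
  # cross-check every M against a direct pairwise-SD computation
  direct <- sapply(c("A", "B", "C"), function(j) {
    mean(sapply(setdiff(c("A", "B", "C"), j),
                function(k) sd(cq3[, j] - cq3[, k])))
  })
  expect_equal(g3$stability$value, unname(direct), tolerance = 1e-12)
})

test_that("geNorm M is invariant to per-sample additive shifts", {
  set.seed(22)
  cq <- toy_cq(matrix(rnorm(40, 25, 1), 10, 4))
  g1 <- genorm(cq, colnames(cq))
  shifted <- unclass(cq) + rnorm(10, 0, 3)  # one constant per sample row
  g2 <- genorm(toy_cq(shifted, assays = colnames(cq)), colnames(cq))
  expect_equal(g2$stability$value, g1$stability$value, tolerance = 1e-12)
  expect_error(genorm(cq, "A1"), "at least 2")
})

test_that("BestKeeper: index correlation, descriptive SD/CV, degenerate candidates", {
  # a single candidate is its own index: r = 1
  v <- c(24, 25, 23, 26, 24.5)
  b1 <- bestkeeper(toy_cq(cbind(A = v)), "A")
  expect_equal(b1$stability$r, 1)
  expect_equal(unname(b1$index), v)

  # constant candidate: SD = 0, CV = 0, r undefined with a reason
  cq <- toy_cq(cbind(A = v, B = rep(24, 5)))
  b2 <- bestkeeper(cq, c("A", "B"))
  expect_equal(b2$stability$value[2], 0)
  expect_equal(b2$stability$cv_percent[2], 0)
  expect_match(b2$stability$reason[2], "zero variance")

  # anti-correlated candidate has the lowest r; frozen hand-computed Pearson:
  # x = {1,2,3,4,5} around 24, D = 24 - x pattern
  x <- c(-2, -1, 0, 1, 2)
  cq4 <- toy_cq(cbind(A = 24 + x, B = 25 + x, C = 23 + x, D = 24 - x))
  b4 <- bestkeeper(cq4, colnames(cq4))
  expect_equal(b4$stability$assay_id[which.min(b4$stability$r)], "D")
  # index = 24 + x/2; cov(D, index) = -sum(x^2)/(n-1) / 2 = -2.5;
  # sd(D) = sqrt(2.5), sd(index) = sqrt(2.5)/2 -> r = -2.5/2.5 = -1
  expect_equal(b4$stability$r[4], -1, tolerance = 1e-12)
})

test_that("NormFinder: zero for identical candidates, planted bias dominates", {
  groups <- setNames(rep(c("HC", "AD"), each = 4), paste0("S", 1:8))
  # all candidates identical across samples: no bias, no variance
  same <- toy_cq(matrix(24, 8, 3), samples = names(groups))
  nf0 <- normfinder(same, colnames(same), groups)
  expect_equal(nf0$stability$value, rep(0, 3))

  set.seed(23)
  base <- matrix(rnorm(8 * 4, 25, 0.3), 8, 4)
  base[groups == "AD", 4] <- base[groups == "AD", 4] + 2  # planted group bias
  cq <- toy_cq(base, samples = names(groups))
  nf <- normfinder(cq, colnames(cq), groups)
  expect_equal(nf$stability$assay_id[which.max(nf$stability$value)], "A4")

  # per-sample additive shifts cancel through sample centering
  shifted <- unclass(cq) + rnorm(8, 0, 5)
  nf2 <- normfinder(toy_cq(shifted, samples = names(groups),
                           assays = colnames(cq)), colnames(cq), groups)
  expect_equal(nf2$stability$value, nf$stability$value, tolerance = 1e-9)

  expect_error(normfinder(cq, c("A1", "A2"), groups), "at least 3")
  expect_warning(normfinder(cq, colnames(cq),
                            setNames(rep("HC", 8), names(groups))),
                 "single group")
})

test_that("cross-method comparison aggregates by mean rank with consistent bookkeeping", {
  cand <- data.frame(assay_id = paste0("m", 1:5), baseline = 22:26,
                     shift = c(0, 0, 0, 0.8, 1.5), sd = c(0.2, 0.25, 0.3, 0.3, 0.3))
  ds <- simulate_cq_dataset(sim_spec(candidates = cand, n_per_group = 25, seed = 31))
  cmp <- aggregate_and_compare(ds, "HC", "AD", k = 3, top = 5)
  expect_equal(nrow(cmp$rankings), choose(5, 3))
  rank_cols <- grep("_rank$", colnames(cmp$rankings), value = TRUE)
  rank_cols <- setdiff(rank_cols, "aggregate_rank")
  # every method's ranks are a permutation of 1..n
  for (cl in rank_cols) {
    expect_equal(sort(cmp$rankings[[cl]]), seq_len(nrow(cmp$rankings)))
  }
  # the aggregate is the rank of the hand-computed mean of per-method ranks
  expect_equal(cmp$rankings$aggregate_rank,
               rank(rowMeans(cmp$rankings[, rank_cols]), ties.method = "first"))
  expect_equal(dim(cmp$spearman), c(5, 5))
  expect_equal(unname(diag(cmp$spearman)), rep(1, 5))
  expect_true(all(cmp$spearman >= -1 & cmp$spearman <= 1))
  expect_equal(nrow(cmp$top), 5 * 5)  # 4 methods + aggregate, top 5 each
  expect_error(aggregate_and_compare(ds, "HC", "AD", k = 9), "exceeds")
})

test_that("methods agreeing by construction reach Spearman 1 and identical top lists", {
  # candidates differing only in independent noise SD order identically under
  # geNorm and BestKeeper: both are driven by the per-candidate scatter
  set.seed(32)
  n <- 30
  cq <- toy_cq(cbind(A = rnorm(n, 24, 0.05), B = rnorm(n, 25, 0.4),
                     C = rnorm(n, 23, 1.2), D = rnorm(n, 26, 3)))
  meta <- data.frame(sample_id = rownames(cq),
                     group = rep(c("HC", "AD"), n / 2), sex = "F", age = 70,
                     cohort = "toy")
  ds <- structure(list(cq = cq, meta = meta,
                       panel = panel_config(colnames(cq),
                                            haemolysis_plasma_marker = "A",
                                            haemolysis_rbc_marker = "A")),
                  class = "mirnorm_dataset")
  cmp <- aggregate_and_compare(ds, "HC", "AD", k = 1, top = 4,
                               methods = c("genorm", "bestkeeper"))
  expect_equal(cmp$spearman["genorm", "bestkeeper"], 1)
  expect_equal(cmp$top$code[cmp$top$method == "genorm"],
               cmp$top$code[cmp$top$method == "bestkeeper"])
})
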