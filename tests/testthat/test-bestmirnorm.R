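test_that("enumeration yields 2^n - 1 bijective bitmask codes", {
  for (n in c(1, 3, 4, 7)) {
    combos <- enumerate_combinations(paste0("m", seq_len(n)))
    expect_equal(length(combos$codes), 2^n - 1)
    expect_equal(sort(combos$table$code), seq_len(2^n - 1))
    # per size, the subset counts match the binomial coefficients
    expect_equal(unname(table(combos$table$size)),
                 unname(choose(n, seq_len(n)))[choose(n, seq_len(n)) > 0],
                 ignore_attr = TRUE)
  }
  one <- enumerate_combinations("m1")
  expect_equal(one$members[[1]], "m1")
  expect_equal(one$table$code, 1L)

  abc <- enumerate_combinations(c("A", "B", "C"))
  expect_equal(abc$members[[5]], c("A", "C"))  # code 5 = bits 0 and 2
  expect_equal(combination_members(5, c("A", "B", "C")), c("A", "C"))
  # codes and member sets are mutually inverse over the whole range
  for (code in abc$codes) {
    expect_equal(combination_members(code, abc$candidates), abc$members[[code]])
  }
  expect_error(enumerate_combinations(character(0)), "empty")
  expect_error(enumerate_combinations(paste0("m", 1:12)), "allow_large")
})

test_that("combination scoring matches the hand-computed two-group toy", {
  # HC target {20,20}, AD {21,23}, reference assay B constant 18:
  # target A -ddCq: HC {0,0}, AD {-1,-3} -> D = 1, dev = 1, sd = sqrt(2)/2
  # target B (self): all zero -> contributes (0, 0, 0)
  ds <- toy_dataset(cbind(A = c(20, 20, 21, 23), B = rep(18, 4)),
                    groups = c("HC", "HC", "AD", "AD"))
  sc <- score_combination(ds, "B", "HC", "AD", min_group_n = 2)
  expect_equal(sc$ks_metric, 0.5)
  expect_equal(sc$dev_metric, 0.5)
  expect_equal(sc$sd_metric, 0.3535534, tolerance = 1e-7)  # mean(0.70711, 0) / 2 targets
  expect_equal(sc$n_targets, 2L)

  # degenerate singleton scored only on itself: identically zero metrics
  ds1 <- toy_dataset(cbind(A = c(20, 21, 22, 23, 24, 25)),
                     groups = rep(c("HC", "AD"), 3))
  s1 <- score_combination(ds1, "A", "HC", "AD", min_group_n = 2)
  expect_equal(c(s1$ks_metric, s1$dev_metric, s1$sd_metric), c(0, 0, 0))

  # identical case and control distributions: KS metric 0
  ds2 <- toy_dataset(cbind(A = rep(c(20, 21, 22), 2), B = rep(18, 6)),
                     groups = rep(c("HC", "AD"), each = 3))
  s2 <- score_combination(ds2, "B", "HC", "AD")
  expect_equal(s2$ks_metric, 0)

  expect_error(score_combination(ds, "B", "HC", "XX"), "unknown group")
  # too few complete samples in every target: explicit unevaluable status
  s3 <- score_combination(ds, "B", "HC", "AD", min_group_n = 5)
  expect_equal(s3$status, "unevaluable")
})

test_that("rank points honour the best = n-1 / worst = 0 scheme with tie averaging", {
  two <- data.frame(code = 1:2, ks_metric = c(0.1, 0.2),
                    dev_metric = c(0.1, 0.2), sd_metric = c(0.1, 0.2))
  rk <- rank_combinations(two, c(1, 1, 1))
  expect_equal(rk$total, c(3, 0))
  expect_equal(rk$final_rank[rk$code == 1], 1L)

  # tied pair shares (2 + 1)/2 = 1.5 points; third gets 0
  ties <- data.frame(code = 1:3, ks_metric = c(0.1, 0.1, 0.3),
                     dev_metric = c(1, 2, 3), sd_metric = c(1, 2, 3))
  rt <- rank_combinations(ties)
  expect_equal(sort(rt$ks_points, decreasing = TRUE), c(1.5, 1.5, 0))
  expect_equal(rt$ks_points, brute_points(rt$ks_metric))

  # per-metric points always sum to n(n-1)/2, ties included
  set.seed(15)
  n <- 40
  rnd <- data.frame(code = 1:n,
                    ks_metric = round(runif(n), 1),  # forced ties
                    dev_metric = runif(n), sd_metric = runif(n))
  rr <- rank_combinations(rnd)
  for (col in c("ks_points", "dev_points", "sd_points")) {
    expect_equal(sum(rr[[col]]), n * (n - 1) / 2)
  }
  expect_equal(rr$ks_points, brute_points(rr$ks_metric))

  expect_warning(rank_combinations(data.frame(
    code = 1:2, ks_metric = c(1, 1), dev_metric = c(1, 2),
    sd_metric = c(1, 2))), "tie")
  expect_error(rank_combinations(two, c(0, 0, 0)), "weights")
  expect_error(rank_combinations(two[1, ]), "at least 2")
})

test_that("final ranking is invariant to uniform weight scaling", {
  set.seed(16)
  scores <- data.frame(code = 1:20, ks_metric = runif(20),
                       dev_metric = runif(20), sd_metric = runif(20))
  r1 <- rank_combinations(scores, c(1, 1, 1))
  r2 <- rank_combinations(scores, c(2, 2, 2))
  r3 <- rank_combinations(scores, c(1, 2, 3))
  expect_equal(r1$code, r2$code)
  expect_false(identical(r1$code, r3$code))  # non-uniform weights do matter here
})

test_that("worsening every metric of a combination never improves its rank", {
  set.seed(17)
  scores <- data.frame(code = 1:15, ks_metric = runif(15),
                       dev_metric = runif(15), sd_metric = runif(15))
  base <- rank_combinations(scores)
  for (victim in c(1L, 8L, 15L)) {
    worse <- scores
    worse[worse$code == victim, c("ks_metric", "dev_metric", "sd_metric")] <-
      worse[worse$code == victim, c("ks_metric", "dev_metric", "sd_metric")] + 0.5
    after <- rank_combinations(worse)
    expect_gte(after$final_rank[after$code == victim],
               base$final_rank[base$code == victim])
  }
})

test_that("brute-force oracle reproduces scores and ranking for small panels", {
  for (n_cand in c(3, 4)) {
    spec <- sim_spec(
      n_per_group = 9,  # 18 samples
      candidates = data.frame(assay_id = paste0("m", seq_len(n_cand)),
                              baseline = seq(22, 26, length.out = n_cand),
                              shift = c(rep(0, n_cand - 1), 1),
                              sd = 0.4),
      seed = 100 + n_cand)
    ds <- simulate_cq_dataset(spec)
    fast <- mirnorm:::.score_all_combinations(ds, "HC", "AD")
    slow <- brute_score_all(ds, "HC", "AD")
    slow <- slow[match(fast$code, slow$code), ]
    for (m in c("ks_metric", "dev_metric", "sd_metric")) {
      expect_equal(fast[[m]], slow[[m]], tolerance = 1e-12)
    }
    # exact KS ties are common (D is a count ratio); round away sub-1e-9
    # accumulation noise so both routes see the same tie structure
    fr <- fast; sr <- slow
    for (m in c("ks_metric", "dev_metric", "sd_metric")) {
      fr[[m]] <- round(fr[[m]], 9); sr[[m]] <- round(sr[[m]], 9)
    }
    expect_equal(rank_combinations(fr)$code, brute_rank(sr))
  }
})

test_that("a 3-stable/2-shifted panel puts only stable candidates on top", {
  ds <- simulate_cq_dataset(sim_spec(
    candidates = planted_panel(5, 3, shift = 1.5, sd = 0.2), seed = 1))
  res <- run_bestmirnorm(ds, "HC", "AD")
  expect_equal(nrow(res$rank_table), 31)
  top <- combination_members(res$rank_table$code[1], ds$panel$candidates)
  expect_false(any(top %in% c("Un1", "Un2")))
})

test_that("with many shifted candidates the stable set stays near the top", {
  # 3 of 7 candidates shifted: the group-SD metric rewards combination size,
  # so a 5-member set diluting one shifted candidate can overtake the pure
  # stable subset — but an all-stable combination stays within the top ranks
  for (s in 1:3) {
    ds <- simulate_cq_dataset(sim_spec(
      candidates = planted_panel(7, 4, shift = 1.5, sd = 0.2), seed = s))
    rt <- run_bestmirnorm(ds, "HC", "AD")$rank_table
    clean <- vapply(rt$code, function(cd) {
      !any(grepl("^Un", combination_members(cd, ds$panel$candidates)))
    }, logical(1))
    expect_lte(min(rt$final_rank[clean]), 4)
  }
})

test_that("the full run ranks 127 combinations and recovers a planted stable set", {
  cand <- data.frame(assay_id = c("St1", "St2", "St3", "St4", "St5", "Un1", "Un2"),
                     baseline = seq(22, 28, 1),
                     shift = c(0, 0, 0, 0, 0, 1.5, 2.0),
                     sd = 0.2)
  ds <- simulate_cq_dataset(sim_spec(candidates = cand, seed = 42))
  res <- run_bestmirnorm(ds, "HC", "AD")
  expect_equal(nrow(res$rank_table), 127)
  expect_equal(nrow(res$code_table), 127)
  top <- combination_members(res$rank_table$code[1], ds$panel$candidates)
  expect_false(any(top %in% c("Un1", "Un2")))
  # membership matrix marks exactly the members of each top combination
  expect_equal(dim(res$top_membership), c(7, 10))
  expect_equal(rownames(res$top_membership)[res$top_membership[, 1]], top)

  # uniform weight scaling leaves the full ordering untouched
  res2 <- run_bestmirnorm(ds, "HC", "AD", weights = c(2, 2, 2))
  expect_equal(res2$rank_table$code, res$rank_table$code)

  # excluding samples really removes them from the scored data
  res3 <- run_bestmirnorm(ds, "HC", "AD",
                          exclude_samples = ds$meta$sample_id[1:4])
  expect_equal(res3$rank_table$n_targets, rep(7L, 127))
  expect_false(identical(res3$rank_table$ks_metric, res$rank_table$ks_metric))
})

test_that("weight grid scan: 25 default weightings and top-k bookkeeping", {
  grid <- default_weight_grid()
  expect_equal(nrow(grid), 25)
  expect_false(any(grid$w_ks == 2 & grid$w_dev == 2 & grid$w_sd == 2))
  expect_false(any(grid$w_ks == 3 & grid$w_dev == 3 & grid$w_sd == 3))
  expect_true(any(grid$w_ks == 1 & grid$w_dev == 1 & grid$w_sd == 1))

  ds <- simulate_cq_dataset(sim_spec(
    candidates = data.frame(assay_id = paste0("m", 1:4),
                            baseline = 23:26, shift = c(0, 0, 0.5, 1), sd = 0.3),
    n_per_group = 20, seed = 5))
  res111 <- run_bestmirnorm(ds, "HC", "AD", top_k = 5)
  scan <- weight_grid_scan(ds, "HC", "AD",
                           grid = data.frame(w_ks = 1, w_dev = 1, w_sd = 1),
                           top_k = 5)
  expect_equal(scan$top$code, res111$rank_table$code[1:5])
  expect_equal(unique(scan$stability$n_weightings), 1L)

  full <- weight_grid_scan(ds, "HC", "AD", top_k = 3)
  expect_equal(nrow(full$top), 25 * 3)
  expect_true(all(full$stability$times_in_top <= 25))
  expect_error(weight_grid_scan(ds, "HC", "AD", grid = data.frame()), "empty")
})
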