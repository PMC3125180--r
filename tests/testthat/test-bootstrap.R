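test_that("replicate profiles densify the per-replicate maxima", {
  pm <- pulldown_matrix(pm_entries(list("P01", "B1", 1, 1, 0.5),
                                   list("P02", "B1", 1, 2, 0.3),
                                   list("P02", "B1", 1, 3, 0.8)))
  prof <- replicate_profile(pm, "B1", 1L, c("P01", "P02", "P03"))
  expect_equal(unname(prof), c(0.5, 0.8, 0))
  # consistency with max_over_fractions on random matrices
  for (seed in 4:6) {
    rpm <- random_pulldown(seed)
    prot <- pd_proteins(rpm)
    for (b in pd_baits(rpm)) {
      p1 <- replicate_profile(rpm, b, 1L, prot)
      v <- max_over_fractions(rpm, b, 1L)
      expect_equal(p1[names(v)], v)
      expect_true(all(p1[setdiff(prot, names(v))] == 0))
    }
  }
})

test_that("null-pool screening excludes correlated replicates", {
  # B2 replicate 1 mirrors B1's profiles (R = 1); B3 is uncorrelated
  pm <- pulldown_matrix(rbind(
    bait_block("B1", list(P01 = c(5, 5, 5), P02 = c(1, 1, 1),
                          P03 = c(3, 3, 3))),
    bait_block("B2", list(P01 = c(5, NA, NA), P02 = c(1, 2, NA),
                          P03 = c(3, NA, 1), P04 = c(NA, 4, 4))),
    bait_block("B3", list(P04 = c(2, 2, 2), P05 = c(4, 4, 4),
                          P06 = c(1, 1, 1)))))
  pool <- build_null_pool(pm, "B1", bootstrap_config(r_threshold = 0.3))
  key <- paste(pool$members$source_bait, pool$members$replicate)
  expect_false("B2 1" %in% key)            # identical profile excluded
  expect_true(all(paste("B3", 1:3) %in% key))

  # membership equals a brute-force all-pairs correlation check
  for (seed in 7:9) {
    rpm <- random_pulldown(seed)
    prot <- pd_proteins(rpm)
    for (b in pd_baits(rpm)) {
      own <- lapply(pd_replicates(rpm, b), function(r)
        replicate_profile(rpm, b, r, prot))
      cands <- c(setdiff(pd_baits(rpm), b), pd_control_id(rpm))
      want <- character(0)
      for (cb in cands) for (r in pd_replicates(rpm, cb)) {
        cand <- replicate_profile(rpm, cb, r, prot)
        cors <- vapply(own, function(p) {
          if (sd(cand) == 0 || sd(p) == 0) 0 else cor(cand, p)
        }, 0)
        if (all(cors < 0.3)) want <- c(want, paste(cb, r))
      }
      got <- tryCatch({
        pool <- build_null_pool(rpm, b)
        paste(pool$members$source_bait, pool$members$replicate)
      }, error = function(e) character(0))
      expect_setequal(got, want)
    }
  }
})

test_that("bootstrap p-values hit the degenerate and enumerable cases", {
  cfg <- bootstrap_config(n_boot = 10000L, seed = 5L)
  # strict dominance: every resample exceeds
  r <- bootstrap_pvalue(c(1, 1, 1), c(0, 0, 0), cfg)
  expect_equal(r$n_exceed, cfg$n_boot)
  expect_equal(r$p_value, 0)
  # all ties: strict inequality never holds
  r0 <- bootstrap_pvalue(c(0, 0, 0), c(0, 0, 0), cfg)
  expect_equal(r0$n_exceed, 0L)
  expect_equal(r0$p_value, 1)
  # exact enumeration oracle: bait (1,0,0) vs pool (0,0,0); the bait median
  # exceeds 0 only when >= 2 of 3 equiprobable draws pick the 1, so
  # P(exceed) = (3*2 + 1)/27 = 7/27 and p = 20/27
  p_true <- 1 - 7 / 27
  se <- sqrt((7 / 27) * (20 / 27) / cfg$n_boot)
  r1 <- bootstrap_pvalue(c(1, 0, 0), c(0, 0, 0), cfg)
  expect_lt(abs(r1$p_value - p_true), 3 * se)
  expect_error(bootstrap_pvalue(c(1, 0), c(0), cfg), "sample_size")
})

test_that("bootstrap is seed-deterministic with per-pair streams", {
  sim <- simulate_pulldowns(sim_config(n_baits = 3, n_proteins = 50,
                                       seed = 2))
  cfg <- bootstrap_config(n_boot = 500L, seed = 17L)
  t1 <- significance_table(sim$pulldowns, cfg)
  t2 <- significance_table(sim$pulldowns, cfg)
  expect_identical(t1, t2)
  t3 <- significance_table(sim$pulldowns, bootstrap_config(n_boot = 500L,
                                                           seed = 18L))
  expect_false(identical(t1$p_value, t3$p_value))
  # p on the 1/n_boot grid, in [0, 1]
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
  expect_true(all(abs(t1$p_value * cfg$n_boot -
                        round(t1$p_value * cfg$n_boot)) < 1e-9))
})

test_that("scaling bait values up never raises the p-value", {
  set.seed(31)
  pool <- rexp(12)
  cfg <- bootstrap_config(n_boot = 4000L, seed = 9L)
  bait <- c(0.5, 1, 2)
  p_prev <- Inf
  for (mult in c(0.5, 1, 2, 8)) {
    p <- bootstrap_pvalue(bait * mult, pool, cfg)$p_value
    expect_lte(p, p_prev)
    p_prev <- p
  }
})

test_that("a planted strong interactor is highly significant", {
  sim <- simulate_pulldowns(sim_config(n_baits = 6, n_proteins = 100,
                                       noise_sigma = 0.3, dropout = 0,
                                       n_reciprocal_pairs = 0, seed = 13))
  tab <- significance_table(sim$pulldowns, bootstrap_config(seed = 13))
  # bait proteins dominate their own pull-downs: expect p ~ 0
  self <- tab[tab$bait == tab$protein, ]
  expect_true(all(self$p_value < 0.001))
})

test_that("a bait with an empty null pool degrades to NA p-values", {
  vals <- list(P01 = c(5, 5, 5), P02 = c(1, 1, 1), P03 = c(2, 2, 2))
  pm <- pulldown_matrix(rbind(bait_block("B1", vals),
                              bait_block("B2", vals)))
  expect_error(build_null_pool(pm, "B1"), "empty null pool")
  w <- capture_warnings(
    tab <- significance_table(pm, bootstrap_config(n_boot = 50L)))
  expect_length(w, 2L)              # one warning per poolless bait
  expect_match(w, "NA p-values", all = TRUE)
  expect_true(all(is.na(tab$p_value)))
  expect_equal(nrow(tab), 6L)
})

test_that("exchangeable null pairs give super-uniform (conservative) p-values", {
  set.seed(77)
  n_pairs <- 1000L
  cfg <- bootstrap_config(n_boot = 400L, seed = 3L)
  p <- vapply(seq_len(n_pairs), function(i) {
    vals <- rexp(3 + 9)             # one exchangeable pool per pair
    bootstrap_pvalue(vals[1:3], vals[4:12], cfg,
                     stream_seed = i)$p_value
  }, 0)
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / n_pairs)
    expect_lte(mean(p < alpha), alpha + 3 * se)
  }
})
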