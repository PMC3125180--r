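test_that("max over fractions picks the per-replicate elution maximum", {
  pm <- pulldown_matrix(pm_entries(
    list("P01", "B1", 1, 1, 0.2), list("P01", "B1", 1, 2, 0.9),
    list("P01", "B1", 1, 3, 0.1), list("P02", "B1", 1, 2, 0.4)))
  v <- max_over_fractions(pm, "B1", 1L)
  expect_equal(unname(v["P01"]), 0.9)
  expect_false("P03" %in% names(v))  # unobserved proteins stay absent
  expect_error(max_over_fractions(pm, "B9", 1L), "unknown bait")
  expect_error(max_over_fractions(pm, "B1", 7L), "unknown replicate")

  # randomized agreement with a brute-force scan
  for (seed in 1:3) {
    rpm <- random_pulldown(seed)
    for (b in pd_baits(rpm)) {
      for (r in pd_replicates(rpm, b)) {
        got <- max_over_fractions(rpm, b, r)
        sub <- rpm[rpm$bait == b & rpm$replicate == r, ]
        want <- tapply(sub$empai, sub$protein, max)
        expect_setequal(names(got), names(want))
        expect_equal(unname(got[names(want)]), as.numeric(want))
      }
    }
  }
})

test_that("control baseline medians per-replicate maxima with zero fill", {
  ctrl <- bait_block(CONTROL_ID, list(P01 = c(1, 2, 3),
                                      P02 = c(3, NA, NA),
                                      P03 = c(2, 4, NA)))
  pm <- pulldown_matrix(rbind(ctrl, pm_entries(list("P01", "B1", 1, 1, 5))),
                        baits = "B1")
  base <- control_baseline(pm)
  expect_equal(unname(base["P01"]), 2)           # median(1,2,3)
  expect_equal(unname(base["P02"]), 0)           # median(3,0,0)
  expect_equal(unname(base["P03"]), 2)           # median(2,4,0)
  expect_equal(unname(baseline_for(base, "P99")), 0)  # never in control
  # drop policy medians observed values only
  base_d <- control_baseline(pm, median_missing = "drop")
  expect_equal(unname(base_d["P02"]), 3)
  expect_equal(unname(base_d["P03"]), 3)

  no_ctrl <- pulldown_matrix(pm_entries(list("P01", "B1", 1, 1, 5)))
  expect_error(control_baseline(no_ctrl), "no control")
  expect_length(control_baseline(no_ctrl, no_control = TRUE), 0L)
})

test_that("median-max follows the hand-arithmetic oracle", {
  pm <- pulldown_matrix(rbind(
    bait_block("B1", list(P01 = c(2, 5, 3), P02 = c(NA, NA, NA))),
    bait_block(CONTROL_ID, list(P01 = c(1, 1, 1)))), baits = "B1")
  base <- control_baseline(pm)
  mm <- median_max(pm, "B1", base)
  r <- mm[mm$protein == "P01", ]
  expect_equal(r$median_max_raw, 3)          # median(2,5,3)
  expect_equal(r$median_max, 2)              # median(1,4,2) after baseline 1
  expect_equal(r$n_reps_present, 3L)

  # a protein observed in 1 of 3 replicates: absent slots count as 0
  pm2 <- pulldown_matrix(bait_block("B1", list(P01 = c(6, NA, NA),
                                               ANCHOR = c(1, 1, 1))))
  mm2 <- median_max(pm2, "B1", setNames(numeric(0), character(0)))
  r2 <- mm2[mm2$protein == "P01", ]
  expect_equal(r2$median_max, 0)
  expect_equal(r2$n_reps_present, 1L)

  # zero baseline: adjusted equals raw
  mm0 <- median_max(pm, "B1", setNames(numeric(0), character(0)))
  expect_equal(mm0$median_max, mm0$median_max_raw)

  # adjustment floors at zero, never negative
  pm3 <- pulldown_matrix(rbind(
    bait_block("B1", list(P01 = c(0.1, 0.1, 0.1))),
    bait_block(CONTROL_ID, list(P01 = c(5, 5, 5)))), baits = "B1")
  mm3 <- median_max(pm3, "B1", control_baseline(pm3))
  expect_equal(mm3$median_max[mm3$protein == "P01"], 0)
})

test_that("pseudo-confidence normalizes by the bait, or top prey when unobserved", {
  pm <- pulldown_matrix(bait_block("B1", list(
    B1 = c(4, 4, 4), P01 = c(2, 2, 2), P02 = c(1, 1, 1))))
  sc <- pseudo_confidence(median_max(pm, "B1",
                                     setNames(numeric(0), character(0))))
  expect_equal(sc$score[sc$protein == "B1"], 1)   # self-normalization
  expect_equal(sc$score[sc$protein == "P01"], 0.5)
  expect_equal(unique(sc$normalizer_source), "bait_median_max")

  # bait never observed (the unobservable-bait case): top prey normalizes
  pm2 <- pulldown_matrix(bait_block("B2", list(
    P01 = c(3, 3, 3), P02 = c(1.5, 1.5, 1.5))))
  sc2 <- pseudo_confidence(median_max(pm2, "B2",
                                      setNames(numeric(0), character(0))))
  expect_equal(sc2$score[sc2$protein == "P01"], 1)
  expect_equal(sc2$score[sc2$protein == "P02"], 0.5)
  expect_equal(unique(sc2$normalizer_source), "max_prey")
})

test_that("high-confidence filter enforces triplicate, positivity and the control", {
  pm <- pulldown_matrix(rbind(
    bait_block("B1", list(
      B1 = c(4, 4, 4),
      GOOD = c(2, 2, 2),          # above control, all reps -> kept
      TWO = c(9, 9, NA),          # only 2 of 3 replicates -> rejected
      TINY = c(.1, .1, .1),       # present 3x but below control -> rejected
      EQ = c(1, 1, 1))),          # exactly equal to control -> rejected (bait not sticky)
    bait_block(CONTROL_ID, list(TINY = c(2, 2, 2), EQ = c(1, 1, 1)))),
    baits = "B1")
  conf <- high_confidence_filter(pm)
  keep <- conf$protein[conf$high_confidence & conf$bait == "B1"]
  expect_setequal(keep, c("B1", "GOOD"))
  expect_false(any(conf$dashed))
})

test_that("sticky-bait rule keeps equal-to-control prey as dashed edges", {
  # bait itself prominent in the control (the column-binding bait case):
  # equality edges survive only for prey present in all control replicates
  pm <- pulldown_matrix(rbind(
    bait_block("RoO", list(
      RoO = c(5, 5, 5),
      EQ_FULL = c(1, 1, 1),       # = control, prey in all 3 control reps -> dashed edge
      EQ_PART = c(2, 2, 2),       # = control, prey in 1 control rep -> rejected
      ABOVE = c(3, 3, 3))),       # above control -> plain edge
    bait_block(CONTROL_ID, list(RoO = c(4, 4, 4),
                                EQ_FULL = c(1, 1, 1),
                                EQ_PART = c(2, NA, NA),
                                ABOVE = c(1, 1, 1)))),
    baits = "RoO")
  conf <- high_confidence_filter(pm)
  row <- function(p) conf[conf$protein == p & conf$bait == "RoO", ]
  expect_true(row("EQ_FULL")$high_confidence)
  expect_true(row("EQ_FULL")$dashed)
  # EQ_PART has baseline median(2,0,0)=0 -> raw 2 > 0: kept as a plain edge
  expect_true(row("EQ_PART")$high_confidence)
  expect_false(row("EQ_PART")$dashed)
  expect_true(row("ABOVE")$high_confidence)
  expect_false(row("ABOVE")$dashed)
  expect_error(high_confidence_filter(pm, k_reps = 4), "RoO")
})

test_that("scoring is monotone, scale-equivariant and control-neutral at zero", {
  pm <- random_pulldown(21)
  conf <- high_confidence_filter(pm)

  # monotonicity: raising one raw value never lowers that protein's score
  target <- conf[conf$median_max > 0, ][1, ]
  pm_up <- pm
  hit <- pm_up$protein == target$protein & pm_up$bait == target$bait
  pm_up$empai[hit] <- pm_up$empai[hit] * 3
  conf_up <- high_confidence_filter(pm_up)
  up <- conf_up[conf_up$protein == target$protein &
                  conf_up$bait == target$bait, ]
  expect_gte(up$median_max, target$median_max)

  # scale equivariance: c * emPAI scales median-max by c, scores unchanged
  pm_scaled <- pm
  pm_scaled$empai <- pm_scaled$empai * 2.5
  conf_s <- high_confidence_filter(pm_scaled)
  key <- function(d) paste(d$bait, d$protein)
  m <- match(key(conf), key(conf_s))
  expect_equal(conf_s$median_max[m], conf$median_max * 2.5,
               tolerance = 1e-12)
  expect_equal(conf_s$score[m], conf$score, tolerance = 1e-12)
  expect_identical(conf_s$high_confidence[m], conf$high_confidence)

  # with an empty control the adjusted pipeline equals the unadjusted one
  no_ctrl <- pulldown_matrix(pm[pm$bait != pd_control_id(pm), ],
                             baits = pd_baits(pm))
  conf_nc <- high_confidence_filter(no_ctrl, no_control = TRUE)
  expect_equal(conf_nc$median_max, conf_nc$median_max_raw)
})

test_that("replicate agreement matches set arithmetic", {
  pm <- pulldown_matrix(rbind(
    bait_block("SAME", list(P01 = c(1, 1, 1), P02 = c(1, 1, 1))),
    bait_block("DISJ", list(P01 = c(1, NA, NA), P02 = c(NA, 1, NA),
                            P03 = c(NA, NA, 1)))))
  ag <- replicate_agreement(pm, no_control = TRUE)
  expect_equal(ag$agreement_raw[ag$bait == "SAME"], 1)
  expect_equal(ag$agreement_raw[ag$bait == "DISJ"], 0)

  # {A,B,C} vs {B,C,D} twice, one pair per replicate pair: jaccard 2/4
  pm2 <- pulldown_matrix(rbind(
    bait_block("B1", list(A = c(1, NA), B = c(1, 1), C = c(1, 1),
                          D = c(NA, 1)), k = 2L)))
  ag2 <- replicate_agreement(pm2, no_control = TRUE)
  expect_equal(ag2$agreement_raw, 0.5)
  ag2m <- replicate_agreement(pm2, denominator = "min", no_control = TRUE)
  expect_equal(ag2m$agreement_raw, 2 / 3)
})

test_that("apms_score assembles a coherent fit object", {
  sim <- simulate_pulldowns(sim_config(n_baits = 3, n_proteins = 60,
                                       seed = 9))
  fit <- apms_score(sim$pulldowns)
  expect_s3_class(fit, "apms_fit")
  expect_identical(fit$confidence,
                   high_confidence_filter(sim$pulldowns))
  co <- coef(fit)
  expect_true(all(co >= 0))
  expect_match(names(co)[1], "->", fixed = TRUE)
  s <- summary(fit)
  expect_equal(s$n_edges, length(co))
  expect_output(print(fit), "high-confidence edges")
})
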