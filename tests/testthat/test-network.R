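make_conf <- function(edges, dashed = rep(FALSE, nrow(edges))) {
  data.frame(bait = edges[, 1], prey = NA, protein = edges[, 2],
             score = seq(0.9, 0.1, length.out = nrow(edges)),
             dashed = dashed, high_confidence = TRUE,
             stringsAsFactors = FALSE)
}

test_that("network assembly counts nodes/edges and flags reciprocals", {
  conf <- make_conf(cbind(c("A", "A"), c("X", "Y")))
  net <- build_network(conf)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  conf2 <- make_conf(cbind(c("A", "B", "A"), c("B", "A", "A")))
  net2 <- build_network(conf2)
  expect_true(all(net2$edges$reciprocal))
  expect_equal(nrow(net2$edges), 2L)       # self-edge A->A dropped
  expect_true("A" %in% net2$nodes$protein) # bait node survives

  # recount oracle on a simulated fit
  sim <- simulate_pulldowns(sim_config(n_baits = 4, n_proteins = 80,
                                       seed = 15))
  fit <- apms_score(sim$pulldowns)
  net3 <- build_network(fit, roles = sim$roles)
  hc <- fit$confidence[fit$confidence$high_confidence &
                         fit$confidence$protein != fit$confidence$bait, ]
  expect_equal(nrow(net3$edges), nrow(hc))
  expect_setequal(net3$nodes$protein,
                  unique(c(pd_baits(sim$pulldowns), hc$protein)))
})

test_that("reciprocal rate counts observed over possible bait pairs", {
  # A<->B reciprocal, A->C one-way, D isolated: 1 observed of 2 possible
  conf <- make_conf(cbind(c("A", "B", "A"), c("B", "A", "C")))
  conf <- rbind(conf, transform(make_conf(cbind("D", "Z")), score = 0.5))
  net <- build_network(conf)
  rr <- reciprocal_rate(net, bait_set = c("A", "B", "C", "D"))
  expect_equal(rr$observed, 1L)
  expect_equal(rr$possible, 2L)
  expect_equal(rr$rate, 0.5)

  # no bait-bait edge at all -> undefined
  rr0 <- reciprocal_rate(build_network(make_conf(cbind("A", "X"))),
                         bait_set = c("A", "B"))
  expect_equal(rr0$possible, 0L)
  expect_true(is.na(rr0$rate))

  # random fixtures: equals a brute-force pair scan
  set.seed(41)
  baits <- LETTERS[1:6]
  for (i in 1:5) {
    pairs <- expand.grid(b = baits, p = baits, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$b != pairs$p, , drop = FALSE]
    pairs <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    net <- build_network(make_conf(as.matrix(pairs)))
    rr <- reciprocal_rate(net, bait_set = baits)
    obs <- poss <- 0L
    for (a in seq_along(baits)) for (b in seq_along(baits)) {
      if (a >= b) next
      ab <- any(pairs$b == baits[a] & pairs$p == baits[b])
      ba <- any(pairs$b == baits[b] & pairs$p == baits[a])
      if (ab || ba) poss <- poss + 1L
      if (ab && ba) obs <- obs + 1L
    }
    expect_equal(rr$observed, obs)
    expect_equal(rr$possible, poss)
    expect_lte(rr$observed, rr$possible)
  }
})

test_that("functional agreement counts same-role edges", {
  conf <- make_conf(cbind(c("A", "A", "B"), c("X", "Y", "X")))
  net <- build_network(conf)
  roles_all <- c(A = "r1", B = "r1", X = "r1", Y = "r1")
  expect_equal(functional_agreement(net, roles_all), 1)
  roles_bip <- c(A = "r1", B = "r1", X = "r2", Y = "r2")
  expect_equal(functional_agreement(net, roles_bip), 0)
  # mixed hand count: A-X agree, A-Y disagree, B-X unannotated
  roles_mix <- c(A = "r1", X = "r1", Y = "r2")
  expect_equal(functional_agreement(net, roles_mix), 1 / 3)
  expect_equal(functional_agreement(net, roles_mix,
                                    drop_unannotated = TRUE), 1 / 2)
})

test_that("permutation test matches exact enumeration on a 4-node toy", {
  # nodes A,B share role r1 and C,D share r2; both edges A->B, C->D agree
  # under the true labeling (observed agreement 1).  Of the 6 distinct
  # labelings of the multiset {r1,r1,r2,r2}, exactly 2 keep both pairs
  # same-role, so the exact tail probability P(perm >= 1) is 1/3
  conf <- make_conf(cbind(c("A", "C"), c("B", "D")))
  net <- build_network(conf)
  roles <- c(A = "r1", B = "r1", C = "r2", D = "r2")
  res <- permutation_test(net, roles, n_perm = 20000L, seed = 4L)
  expect_equal(res$observed_agreement, 1)
  se <- sqrt((1 / 3) * (2 / 3) / res$n_perm)
  expect_lt(abs(res$p_value - 1 / 3), 3 * se)

  # all nodes one role: every permutation ties the observed value, p = 1
  roles1 <- c(A = "r", B = "r", C = "r", D = "r")
  res1 <- permutation_test(net, roles1, n_perm = 200L, seed = 1L)
  expect_equal(res1$observed_agreement, 1)
  expect_equal(res1$p_value, 1)

  # observed below the permutation mean: p near 1
  roles_bad <- c(A = "r1", B = "r2", C = "r1", D = "r2")
  res_bad <- permutation_test(net, roles_bad, n_perm = 2000L, seed = 2L)
  expect_equal(res_bad$observed_agreement, 0)
  expect_equal(res_bad$p_value, 1)

  # node relabeling leaves the p-value distribution unchanged
  conf_rl <- make_conf(cbind(c("N1", "N3"), c("N2", "N4")))
  net_rl <- build_network(conf_rl)
  roles_rl <- c(N1 = "r1", N2 = "r1", N3 = "r2", N4 = "r2")
  res_rl <- permutation_test(net_rl, roles_rl, n_perm = 20000L, seed = 4L)
  expect_equal(res_rl$p_value, res$p_value)
})

test_that("profile correlations follow textbook Pearson on aligned vectors", {
  pm <- pulldown_matrix(rbind(
    bait_block("B1", list(B1 = c(4, 4, 4), P01 = c(2, 2, 2),
                          P02 = c(1, 1, 1))),
    bait_block("B2", list(B2 = c(8, 8, 8), P01 = c(4, 4, 4),
                          P02 = c(2, 2, 2)))))
  fit <- apms_score(pm, no_control = TRUE)
  r <- profile_correlations(fit)
  expect_equal(diag(r), c(B1 = 1, B2 = 1))
  # identical profiles up to scale: R = 1 on the union index
  conf <- fit$confidence
  v1 <- v2 <- setNames(rep(0, length(unique(conf$protein))),
                       sort(unique(conf$protein)))
  c1 <- conf[conf$bait == "B1", ]; v1[c1$protein] <- c1$score
  c2 <- conf[conf$bait == "B2", ]; v2[c2$protein] <- c2$score
  expect_equal(r["B1", "B2"], cor(v1, v2))
})

test_that("degree summary reports the network means", {
  net <- build_network(make_conf(cbind(c("A", "A"), c("X", "Y"))))
  d <- degree_summary(net)
  expect_equal(unlist(d[c("n_baits", "n_prey", "n_edges")]),
               c(n_baits = 1, n_prey = 2, n_edges = 2))
  expect_equal(d$mean_prey_per_bait, 2.0)
  expect_equal(d$mean_baits_per_prey, 1.0)

  empty <- build_network(data.frame(bait = "A", protein = "A", score = 1,
                                    dashed = FALSE, high_confidence = TRUE))
  d0 <- degree_summary(empty)
  expect_equal(d0$n_edges, 0L)
  expect_true(is.na(d0$mean_baits_per_prey))
})
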