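test_that("the diploid offspring rule matches the gamete-production table", {
  expect_equal(diploid_offspring_rule("Aa", s = 0.3, d = 1),
               list(viability = 1, p_drive = 1))
  expect_equal(diploid_offspring_rule("AA", s = 0.3),
               list(viability = 0.7, p_drive = 1))
  expect_equal(diploid_offspring_rule("aa", s = 0.3),
               list(viability = 1, p_drive = 0))
  r <- diploid_offspring_rule("Aa", s = 0.3, d = 0.9, h = 0.1)
  expect_equal(r$viability, 0.9)
  expect_equal(r$p_drive, 0.9)
})

test_that("family frequencies stay normalized through the recursion", {
  model <- drivesim:::sib_homing_model(sib_params(0.6, 0.5, d = 0.9, h = 0.1))
  F_freq <- rep(1 / 16, 16)
  for (g in 1:20) {
    res <- next_generation_family(F_freq, model)
    F_freq <- res$F_freq
    expect_equal(sum(F_freq), 1, tolerance = 1e-12)
    expect_true(all(F_freq >= 0))
  }
})

test_that("with m = 0 the family model reproduces the two-sex one-locus homing recursion", {
  s <- 0.4
  fam <- run_sib_homing(sib_params(s, m = 0, init_Q = 0),
                        stop = stopping_rule(60, delta_tolerance = 0))
  dip <- run_one_locus_homing(s, sexes = 2, init_drive = 0.01,
                              stop = stopping_rule(60, delta_tolerance = 0))
  # haploid-pool allele frequency equals the diploid model's gamete/zygote
  # frequency one half-step apart; compare drive trajectories
  a_fam <- fam$trajectory$A
  a_dip <- dip$trajectory$A
  expect_equal(a_fam[2:50], a_dip[2:50], tolerance = 1e-9)
})

test_that("an enforced-sib-mating population purges a lethal drive", {
  # Q fixed, m = 1, s = 1: all sib-mated AA families die; drive is purged
  res <- run_sib_homing(sib_params(1, m = 1, init_Q = 1, init_drive = 0.3),
                        stop = stopping_rule(5000))
  expect_equal(res$outcome$allele_status[["A"]], "lost")
})

test_that("analytic classification reproduces the printed thresholds", {
  expect_equal(analytic_classification(0.3, 0.5)$regime, "fixed")
  poly <- analytic_classification(0.75, 0.5)
  expect_equal(poly$regime, "polymorphic")
  expect_equal(poly$frequency, 1 / 3)
  expect_equal(analytic_classification(0.2, 0.95)$regime, "lost")
  expect_equal(analytic_classification(0.2, 1)$regime, "lost")
  expect_equal(analytic_classification(0.5, 0)$regime, "fixed")
})

test_that("long-run recursion outcomes with Q fixed match the analytic classification", {
  cases <- expand.grid(s = c(0.1, 0.3, 0.55, 0.75, 0.9),
                       m = c(0.2, 0.5, 0.95))
  stop <- stopping_rule(2e4)
  for (i in seq_len(nrow(cases))) {
    s <- cases$s[i]; m <- cases$m[i]
    want <- analytic_classification(s, m)
    res <- run_sib_homing(sib_params(s, m, init_Q = 1, init_drive = 0.01),
                          stop)
    a <- res$outcome$final_frequencies[["A"]]
    label <- sprintf("s=%.2f m=%.2f", s, m)
    if (want$regime == "fixed") {
      expect_gt(a, 1 - 1e-6, label = label)
    } else if (want$regime == "lost") {
      expect_lt(a, 1e-6, label = label)
    } else {
      expect_equal(a, want$frequency, tolerance = 1e-3, label = label)
    }
  }
})

test_that("Q frequency is frozen once the drive fixes", {
  res <- run_sib_homing(sib_params(0.2, 0.5), stop = stopping_rule(2000))
  traj <- res$trajectory
  expect_equal(res$outcome$allele_status[["A"]], "fixed")
  post <- traj$Q[traj$A >= 1 - 1e-8]
  expect_lt(diff(range(post)), 1e-6)
})

test_that("mean fitness is 1 - s when the drive fixes and 1 when it is purged", {
  fixed <- run_sib_homing(sib_params(0.3, 0.5), stop = stopping_rule(2000))
  expect_equal(fixed$outcome$mean_fitness, 0.7, tolerance = 1e-6)
  purged <- run_sib_homing(sib_params(0.5, 0.95), stop = stopping_rule(1e5))
  expect_equal(purged$outcome$allele_status[["A"]], "lost")
  expect_equal(purged$outcome$mean_fitness, 1, tolerance = 1e-6)
})

test_that("type-M comparison has a monotone blocking boundary", {
  expect_false(type_m_comparison(0, stop = stopping_rule(2000)))
  expect_true(type_m_comparison(0.9, stop = stopping_rule(1e4)))
})

test_that("one family generation agrees with the individual-based simulator", {
  set.seed(1127)
  s <- 0.3; m <- 0.5; d <- 0.9; h <- 0.1
  model <- drivesim:::sib_homing_model(sib_params(s, m, d, h))
  # a deliberately asymmetric starting state
  F_freq <- (1:16)^1.3; F_freq <- F_freq / sum(F_freq)
  det <- next_generation_family(F_freq, model)$F_freq
  n_fam <- 2e4
  obs <- wf_next_sib_family(F_freq, s, m, d, h, n_fam, brood = 200L)
  # progeny are sampled in family broods, so between-family sampling
  # dominates: the effective sample size is the number of families
  expect_within_sampling_error(obs, det, n_fam)
})
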