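test_that("male gamete distributions follow the homing and blocking rules", {
  g <- male_gamete_distribution("AaBbrr", d = 1)
  expect_equal(unname(g["ABr"]), 1)
  expect_equal(sum(g), 1)

  g_blocked <- male_gamete_distribution("AaBbRr", d = 1)
  expect_equal(unname(g_blocked), rep(1 / 8, 8))

  g9 <- male_gamete_distribution("AaBbrr", d = 0.9)
  expect_equal(unname(g9[c("ABr", "Abr", "aBr", "abr")]),
               c(0.81, 0.09, 0.09, 0.01))

  # single-locus heterozygotes from Table rows
  expect_equal(unname(male_gamete_distribution("Aabbrr")["Abr"]), 1)
  expect_equal(unname(male_gamete_distribution("aaBbrr")["aBr"]), 1)
})

test_that("fitness is multiplicative over drive loci and sex-restricted", {
  p <- drive_params(0.4, 0.3, introduction = "simultaneous")
  expect_equal(genotype_fitness("aabbrr", p), 1)
  expect_equal(genotype_fitness("AABBrr", p), 0.6 * 0.7)
  expect_equal(genotype_fitness("AABBRR", p), 0.6 * 0.7)  # resistance cost-free
  ph <- drive_params(0.5, 0.5, h = 0.1, introduction = "simultaneous")
  expect_equal(genotype_fitness("AaBbrr", ph), 0.9^2)
  pf <- drive_params(0.4, sex_of_effect = "females_only")
  expect_equal(genotype_fitness("AAbbrr", pf, "male"), 1)
  expect_equal(genotype_fitness("AAbbrr", pf, "female"), 0.6)
})

test_that("a cost-free drive fixes despite resistance; resistance is inert after fixation", {
  res <- run_two_drive(drive_params(0, init_resistance = 0.005),
                       stopping_rule(2000))
  expect_equal(res$outcome$allele_status[["A"]], "fixed")
  traj <- res$trajectory
  post_fix <- traj$R[traj$A >= 1 - 1e-8]
  expect_lt(diff(range(post_fix)), 1e-10)
})

test_that("bisection over the fixation grid agrees with the exhaustive scan", {
  bi <- max_resistance_free_s(1, "both", init_resistance = 0.045,
                              grid_step = 0.05)
  sc <- max_resistance_free_s(1, "both", init_resistance = 0.045,
                              grid_step = 0.05, method = "scan")
  expect_equal(bi$max_s, sc$max_s)
  # monotone boundary: fixation holds below, fails above
  expect_true(all(diff(sc$grid$fixed) <= 0))
})

test_that("sequential and simultaneous introduction give the same maximum", {
  sq <- max_resistance_free_s(2, "females_only", init_resistance = 0.005,
                              grid_step = 0.05, introduction = "sequential")
  sm <- max_resistance_free_s(2, "females_only", init_resistance = 0.005,
                              grid_step = 0.05, introduction = "simultaneous")
  expect_lte(abs(sq$max_s - sm$max_s), 0.05)  # within one grid step
})

test_that("the resistance-free maximum drops with higher initial resistance and a second drive helps", {
  lo <- max_resistance_free_s(1, "both", init_resistance = 0.005,
                              grid_step = 0.02)
  hi <- max_resistance_free_s(1, "both", init_resistance = 0.065,
                              grid_step = 0.02)
  expect_gte(lo$max_s, hi$max_s)
  two <- max_resistance_free_s(2, "both", init_resistance = 0.005,
                               grid_step = 0.02, introduction = "sequential")
  expect_gte(two$max_s, lo$max_s)
})

test_that("with no resistance a male-limited drive fixes below the one-sex floor and is polymorphic above it", {
  res <- run_two_drive(drive_params(0.45, init_resistance = 0),
                       stopping_rule(5000))
  expect_equal(res$outcome$allele_status[["A"]], "fixed")
  # above s = 0.5 the non-driving sex keeps wild-type alleles in play
  hi <- run_two_drive(drive_params(0.9, init_resistance = 0),
                      stopping_rule(5000))
  expect_equal(hi$outcome$allele_status[["A"]], "polymorphic")
})

test_that("larger s leaves more resistance behind among fixing runs", {
  finals <- sapply(c(0.1, 0.25, 0.38), function(s) {
    res <- run_two_drive(drive_params(s, init_resistance = 0.005,
                                      sex_of_effect = "both"))
    stopifnot(res$outcome$resistance_free)
    res$outcome$final_frequencies[["R"]]
  })
  expect_true(all(diff(finals) > 0))
})
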