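test_that("offspring viability implements the three density zones", {
  p <- eco_params(b = 3, K = 1e9, sK = 0.4)
  # below K(1-sK): all genotypes survive equally
  expect_equal(offspring_viability("AA", 5e8, p), 1)
  expect_equal(offspring_viability("aa", 5e8, p), 1)
  # above K: relative viability of AA is (1-sb)(1-sK)
  p2 <- eco_params(b = 3, K = 1e9, sb = 0.2, sK = 0.4)
  N <- 2e9
  rel <- offspring_viability("AA", N, p2) / offspring_viability("aa", N, p2)
  expect_equal(rel, 0.8 * 0.6)
  # middle zone: AA viability K(1-sK)/N, others capped at 1
  expect_equal(offspring_viability("Aa", 8e8, p2), 1)
  expect_equal(offspring_viability("AA", 8e8, eco_params(b = 3, sK = 0.4)),
               1e9 * 0.6 / 8e8)
  expect_equal(offspring_viability("aa", 0, p), 1)
})

test_that("a monomorphic population is regulated to the ceiling", {
  traj <- run_ecology(eco_params(b = 3, init_drive = 0, init_resistance = 0),
                      stopping_rule(50))
  expect_equal(traj$population_size[nrow(traj)], 1e9)
  expect_false(attr(traj, "extinct"))
})

test_that("with no viability costs the allele dynamics decouple from ecology", {
  eco <- run_ecology(eco_params(b = 3, init_drive = 0.01,
                                init_resistance = 0.01),
                     stopping_rule(40, delta_tolerance = 0))
  params <- drive_params(0, init_drive = 0.01, init_resistance = 0.01)
  gen <- run_two_drive(params, stopping_rule(40, delta_tolerance = 0))
  expect_equal(eco$A, gen$trajectory$A, tolerance = 1e-9)
  expect_equal(eco$R, gen$trajectory$R, tolerance = 1e-9)
})

test_that("knockdown with fraction 1 is a no-op", {
  kd <- run_ecology(eco_params(b = 3, sK = 0.3,
                               knockdown = list(period = 5, fraction = 1)),
                    stopping_rule(60, delta_tolerance = 0))
  plain <- run_ecology(eco_params(b = 3, sK = 0.3),
                       stopping_rule(60, delta_tolerance = 0))
  expect_equal(kd$A, plain$A, tolerance = 1e-12)
  expect_equal(kd$population_size, plain$population_size, tolerance = 1e-3)
})

test_that("density-independent lethality at low birth rate causes extinction; density-dependent does not", {
  di <- classify_persistence(eco_params(b = 3, sb = 0.4))
  expect_equal(di$outcome, "extinct")
  dd <- classify_persistence(eco_params(b = 3, sK = 0.4))
  expect_equal(dd$outcome, "persists")
  expect_equal(dd$relative_density, 0.6, tolerance = 1e-6)  # 1 - sK
  hi <- classify_persistence(eco_params(b = 10, sb = 0.4))
  expect_equal(hi$outcome, "persists")
})

test_that("drive-frequency trajectories barely differ between DI and DD modes", {
  di <- run_ecology(eco_params(b = 3, sb = 0.4), stop_at_extinction = FALSE)
  dd <- run_ecology(eco_params(b = 3, sK = 0.4))
  n <- min(nrow(di), nrow(dd))
  expect_lt(max(abs(di$A[1:n] - dd$A[1:n])), 0.05)
})

test_that("the ecological scan agrees between bisection and exhaustive search", {
  bi <- max_resistance_free_eco("DI", b = 3, grid_step = 0.05)
  sc <- max_resistance_free_eco("DI", b = 3, grid_step = 0.05,
                                method = "scan")
  expect_equal(bi$max_coefficient, sc$max_coefficient)
  expect_true(all(diff(sc$grid$fixed) <= 0))
})

test_that("under knockdown the density-dependent limit grows as birth rate falls", {
  kd <- list(period = 5, fraction = 0.25)
  lims <- sapply(c(3, 6, 12), function(b)
    max_resistance_free_eco("DD", b = b, knockdown = kd,
                            grid_step = 0.02)$max_coefficient)
  expect_true(all(diff(lims) <= 0))
  # knockdown leaves the density-independent limit unchanged
  di_kd <- max_resistance_free_eco("DI", b = 3, knockdown = kd,
                                   grid_step = 0.02)$max_coefficient
  di <- max_resistance_free_eco("DI", b = 3, grid_step = 0.02)$max_coefficient
  expect_equal(di_kd, di)
})
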