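# Core recursion engine: conservation, neutral limits, and agreement with
# independent oracles.

neutral_one_locus <- function(d = 0.5, w = c(1, 1, 1)) {
  tab <- enumerate_genotypes("A")
  transmit <- matrix(c(0, d, 1), ncol = 1)
  diploid_model(tab, transmit_female = matrix((0:2) / 2, ncol = 1),
                transmit_male = transmit,
                fitness_female = w, fitness_male = w)
}

test_that("neutral Hardy-Weinberg input is a fixed point", {
  tab <- enumerate_genotypes("A")
  model <- neutral_one_locus()
  freq <- drivesim:::hardy_weinberg_state(tab, c(A = 0.3))
  state <- next_generation(list(freq = freq, generation = 0L), model)
  expect_equal(state$freq, freq, tolerance = 1e-14)
  traj <- iterate(freq, model, stopping_rule(100))
  expect_equal(max(traj$generation), 1)  # stops by delta tolerance at once
  expect_true(attr(traj, "converged"))
})

test_that("Mendelian limit: with d = 0.5 and no selection allele frequencies are constant", {
  tab <- enumerate_genotypes(c("A", "B", "R"))
  transmit <- tab$counts / 2
  model <- diploid_model(tab, transmit, transmit)
  set.seed(41)
  for (rep in 1:5) {
    freq <- stats::runif(tab$n); freq <- freq / sum(freq)
    af0 <- allele_frequencies(freq, tab)
    st <- list(freq = freq, generation = 0L)
    for (g in 1:5) st <- next_generation(st, model)
    expect_equal(allele_frequencies(st$freq, tab), af0, tolerance = 1e-12)
    expect_equal(sum(st$freq), 1, tolerance = 1e-12)
  }
})

test_that("a cost-free complete drive strictly increases and fixes", {
  tab <- enumerate_genotypes("A")
  model <- neutral_one_locus(d = 1)
  freq <- drivesim:::hardy_weinberg_state(tab, c(A = 0.1))
  traj <- iterate(freq, model, stopping_rule(200))
  expect_true(all(diff(traj$A) > -1e-15))
  expect_gt(traj$A[nrow(traj)], 1 - 1e-8)
  # from 0.01 it still fixes in finite generations
  traj2 <- iterate(drivesim:::hardy_weinberg_state(tab, c(A = 0.01)),
                   model, stopping_rule(500))
  expect_gt(traj2$A[nrow(traj2)], 1 - 1e-8)
})

test_that("next_generation matches the brute-force enumeration oracle", {
  tab <- enumerate_genotypes(c("A", "B", "R"))
  set.seed(7)
  for (rep in 1:4) {
    d <- stats::runif(1, 0.5, 1)
    params <- drive_params(stats::runif(1), stats::runif(1), d = d,
                           h = stats::runif(1, 0, 0.3),
                           introduction = "simultaneous")
    tf <- drivesim:::two_drive_transmit(tab, d, male = FALSE)
    tm <- drivesim:::two_drive_transmit(tab, d, male = TRUE)
    wf <- drivesim:::two_drive_fitness(tab, params, "female")
    wm <- drivesim:::two_drive_fitness(tab, params, "male")
    model <- diploid_model(tab, tf, tm, wf, wm)
    freq <- stats::runif(tab$n); freq <- freq / sum(freq)
    got <- next_generation(list(freq = freq, generation = 0L), model)$freq
    want <- brute_force_next(freq, tab, tf, tm, wf, wm)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("an inviable population signals an error", {
  tab <- enumerate_genotypes("A")
  model <- neutral_one_locus(d = 1, w = c(0, 0, 0))
  freq <- drivesim:::hardy_weinberg_state(tab, c(A = 0.5))
  expect_error(next_generation(list(freq = freq, generation = 3L), model),
               "inviable")
})

test_that("one generation agrees with the individual-based stochastic simulator", {
  set.seed(20260926)
  tab <- enumerate_genotypes(c("A", "B", "R"))
  params <- drive_params(0.3, 0.2, d = 0.9, h = 0.05,
                         introduction = "simultaneous")
  freq <- drivesim:::hardy_weinberg_state(tab, c(A = 0.2, B = 0.1, R = 0.15))
  model <- drivesim:::two_drive_model(params)
  det <- next_generation(list(freq = freq, generation = 0L), model)$freq
  n_ind <- 1e6
  obs <- wf_next_two_drive(freq, params, n_ind)
  expect_within_sampling_error(obs, det, n_ind)
})
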