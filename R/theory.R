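# Closed-form equilibrium mean-fitness curves across drive systems, used as
# user-facing calculators and as oracles for the recursion modules.

#' Equilibrium mean fitness under a one-sex homing drive
#'
#' A drive distorting in one sex only fixes for `s <= 0.5` (mean fitness
#' `1 - s`); for `0.5 < s < 1` the population stays polymorphic because the
#' non-driving sex keeps producing wild-type gametes, and mean fitness
#' remains at exactly 0.5.
#'
#' @param s drive homozygote fitness reduction in `[0, 1]`.
#' @return equilibrium mean fitness.
#' @export
onesex_homing_mean_fitness <- function(s) {
  stopifnot(all(s >= 0), all(s <= 1))
  ifelse(s <= 0.5, 1 - s, 0.5)
}

#' Equilibrium mean fitness under a two-sex homing drive
#'
#' With complete distortion in both sexes the drive fixes for any `s`, so
#' equilibrium mean fitness is `1 - s`, anywhere from 1 to 0.
#'
#' @param s drive homozygote fitness reduction in `[0, 1]`.
#' @return equilibrium mean fitness.
#' @export
twosex_homing_mean_fitness <- function(s) {
  stopifnot(all(s >= 0), all(s <= 1))
  1 - s
}

#' Equilibrium mean fitness under ClvR
#'
#' ClvR evolution fixes the nonfunctional allele and leaves C at the
#' overdominant frequency `1/(1 + sigma)`; equilibrium mean fitness is
#' `1/(1 + sigma)`, with floor 0.5 at `sigma = 1` (only Cc survives).
#'
#' @param sigma CC fitness reduction in `[0, 1]`.
#' @return equilibrium mean fitness.
#' @export
clvr_mean_fitness <- function(sigma) {
  stopifnot(all(sigma >= 0), all(sigma <= 1))
  1 / (1 + sigma)
}

#' Analytic drive-outcome thresholds under enforced sib mating
#'
#' @param m sib-mating fraction, `0 < m <= 1`.
#' @return list with `fixation_bound` (`1 - m`: the drive fixes for
#'   `s` below it), `loss_bound` (`min(1/m - 1, 1)`: the drive is lost for
#'   `s` above it), and `polymorphic_frequency`, the function
#'   `s -> 1/s - m/(1 - m)` valid between the bounds.
#' @export
sib_thresholds <- function(m) {
  stopifnot(m > 0, m <= 1)
  list(fixation_bound = 1 - m,
       loss_bound = min(1 / m - 1, 1),
       polymorphic_frequency = function(s) 1 / s - m / (1 - m))
}

#' One-locus homing-drive recursion (diploid sexes)
#'
#' Reference recursion used to cross-check the closed forms: a single drive
#' locus with distortion in males only (`sexes = 1`) or in both sexes
#' (`sexes = 2`), viability cost `s` in drive homozygotes of both sexes.
#'
#' @param s drive homozygote fitness reduction.
#' @param sexes 1 (male-limited homing) or 2 (homing in both sexes).
#' @param d distortion.
#' @param init_drive initial drive-allele frequency.
#' @param stop a [stopping_rule()].
#' @return list with `trajectory` and `outcome`.
#' @export
run_one_locus_homing <- function(s, sexes = 1, d = 1, init_drive = 0.01,
                                 stop = stopping_rule(1e4)) {
  stopifnot(sexes %in% c(1, 2))
  table <- enumerate_genotypes("A")
  transmit_plain <- matrix((0:2) / 2, ncol = 1)
  transmit_drive <- matrix(c(0, d, 1), ncol = 1)
  w <- c(1, 1, 1 - s)
  model <- diploid_model(
    table,
    transmit_female = if (sexes == 2) transmit_drive else transmit_plain,
    transmit_male = transmit_drive,
    fitness_female = w, fitness_male = w)
  freq <- hardy_weinberg_state(table, c(A = init_drive))
  traj <- iterate(freq, model, stop)
  list(trajectory = traj, outcome = outcome_summary(traj, drive_loci = "A"))
}
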