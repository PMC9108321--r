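# Haploid-sex homing drive (A/a) confronting a sib-mating allele (Q/q).
# Sexes are haploid; a mated pair forms a brief diploid in which homing
# (Aa -> drive gametes with probability d) and viability effects (AA progeny
# survive with probability 1 - s) act. Q mothers force a fraction m of their
# progeny to sib mate.

#' Parameters of the sib-mating homing model
#'
#' @param s viability reduction of progeny from AA diploids, in `[0, 1]`.
#' @param m sib-mating fraction enforced by Q mothers, in `[0, 1]`.
#' @param d segregation distortion in `[0.5, 1]`.
#' @param h viability reduction of progeny from Aa diploids.
#' @param init_drive,init_Q initial allele frequencies.
#' @return object of class `sib_params`.
#' @export
sib_params <- function(s, m, d = 1, h = 0, init_drive = 0.01, init_Q = 0.01) {
  stopifnot(s >= 0, s <= 1, m >= 0, m <= 1, d >= 0.5, d <= 1, h >= 0, h <= 1,
            init_drive >= 0, init_drive <= 1, init_Q >= 0, init_Q <= 1)
  structure(list(s = s, m = m, d = d, h = h,
                 init_drive = init_drive, init_Q = init_Q),
            class = "sib_params")
}

#' Offspring rule of a drive-locus diploid
#'
#' The diploid phase of the haploid-sex homing model: `aa` has viability 1
#' and produces only `a` progeny; `Aa` has viability `1 - h` and produces
#' `A` progeny with marginal probability `d` (homing is a germline
#' conversion event: with probability `2d - 1` the germline converts and
#' yields only `A`, otherwise it segregates Mendelianly); `AA` has viability
#' `1 - s` and produces only `A`. All other loci segregate Mendelianly.
#'
#' @param genotype drive-locus diploid genotype: `"aa"`, `"Aa"` or `"AA"`
#'   (or the allele count 0, 1, 2).
#' @param s,d,h model parameters as in [sib_params()].
#' @return list with `viability` and `p_drive`, the probability that a
#'   haploid progeny carries the drive allele.
#' @export
diploid_offspring_rule <- function(genotype, s, d = 1, h = 0) {
  count <- if (is.numeric(genotype)) genotype
           else sum(strsplit(genotype, "")[[1]] == "A")
  stopifnot(count %in% 0:2)
  list(viability = c(1, 1 - h, 1 - s)[count + 1L],
       p_drive = c(0, d, 1)[count + 1L])
}

# Homing is a germline conversion event: with probability c = 2d - 1 the Aa
# germline is converted and yields only drive gametes, otherwise it
# segregates Mendelianly; the marginal drive-gamete fraction is d. Random
# mating only sees the marginal, but the conversion state is shared by the
# gametes of one diploid, so sib-mated pairs see the mixture.
homing_components <- function(a_count, d, transmit_rest) {
  if (a_count != 1L || d == 1)
    return(list(list(weight = 1,
                     transmit = c(A = c(0, d, 1)[a_count + 1L], transmit_rest))))
  conv <- 2 * d - 1
  list(list(weight = conv, transmit = c(A = 1, transmit_rest)),
       list(weight = 1 - conv, transmit = c(A = 0.5, transmit_rest)))
}

sib_homing_model <- function(params) {
  family_model(c("A", "Q"), function(dip) {
    rule <- diploid_offspring_rule(dip[["A"]], params$s, params$d, params$h)
    list(viability = rule$viability,
         components = homing_components(dip[["A"]], params$d,
                                        c(Q = dip[["Q"]] / 2)))
  }, sib_locus = "Q", m = params$m)
}

#' Run the sib-mating homing recursion
#'
#' @param params a [sib_params()].
#' @param stop a [stopping_rule()]; the default caps at `1e5` generations.
#' @return list with `trajectory` and `outcome` (an [outcome_summary()]).
#' @export
run_sib_homing <- function(params, stop = stopping_rule(1e5)) {
  traj <- run_family(sib_homing_model(params),
                     c(A = params$init_drive, Q = params$init_Q), stop)
  list(trajectory = traj, outcome = outcome_summary(traj, drive_loci = "A"))
}

#' Analytic outcome of the homing drive under enforced sib mating
#'
#' With sib mating at level `m` (the Q allele fixed), the drive fixes if
#' `s < 1 - m`, is lost if `s > 1/m - 1`, and for
#' `1 - m < s < min(1/m - 1, 1)` a polymorphic equilibrium exists at drive
#' frequency `1/s - m/(1 - m)`. The polymorphic-frequency expression is
#' continuous with both boundaries (it equals 1 at `s = 1 - m` and 0 at
#' `s = 1/m - 1`), so the classification clamps it to `[0, 1]`.
#'
#' @param s drive homozygote viability reduction.
#' @param m sib-mating fraction (`m = 1` loses any costly drive; `m = 0`
#'   fixes any drive).
#' @return list with `regime` (`"fixed"`, `"lost"` or `"polymorphic"`) and
#'   `frequency` (the equilibrium drive frequency).
#' @export
analytic_classification <- function(s, m) {
  stopifnot(s >= 0, s <= 1, m >= 0, m <= 1)
  if (m == 0) return(list(regime = "fixed", frequency = 1))
  if (m == 1) {
    return(if (s > 0) list(regime = "lost", frequency = 0)
           else list(regime = "fixed", frequency = 1))
  }
  if (s == 0) return(list(regime = "fixed", frequency = 1))
  freq <- 1 / s - m / (1 - m)
  if (freq >= 1) list(regime = "fixed", frequency = 1)
  else if (freq <= 0) list(regime = "lost", frequency = 0)
  else list(regime = "polymorphic", frequency = freq)
}

# Q counts as selected once its frequency exceeds 10x its initial value by
# the generation cap; outcomes are near all-or-none, so the classifier is
# threshold-insensitive.
q_invaded <- function(traj, init_Q) {
  unname(final_alleles(traj)["Q"] > 10 * init_Q)
}

#' Smallest drive cost at which sib mating is selected
#'
#' Scans the drive homozygote cost `s` on a grid and returns the smallest
#' value at which the sib-mating allele Q invades (final frequency above ten
#' times its initial value at the generation cap). Invasion is monotone in
#' `s`, so the default search bisects over the grid.
#'
#' @param m sib-mating fraction enforced by Q.
#' @param d,h drive parameters.
#' @param init_drive,init_Q initial frequencies.
#' @param grid_step grid increment for `s`.
#' @param stop a [stopping_rule()].
#' @param method `"bisect"` or `"scan"`.
#' @return list with `threshold_s` (NA if Q never invades on the grid) and,
#'   for the scan method, the full grid.
#' @export
sib_invasion_threshold <- function(m, d = 1, h = 0,
                                   init_drive = 0.01, init_Q = 0.01,
                                   grid_step = 0.01,
                                   stop = stopping_rule(1e5),
                                   method = c("bisect", "scan")) {
  method <- match.arg(method)
  grid <- seq(grid_step, 1, by = grid_step)
  invades <- function(s) {
    res <- run_sib_homing(sib_params(s, m, d, h, init_drive, init_Q), stop)
    q_invaded(res$trajectory, init_Q)
  }
  if (method == "bisect") {
    k <- bisect_largest_true(grid, function(s) !invades(s))
    list(threshold_s = if (k == length(grid)) NA_real_ else grid[k + 1L])
  } else {
    inv <- vapply(grid, invades, logical(1))
    list(threshold_s = if (any(inv)) grid[min(which(inv))] else NA_real_,
         grid = data.frame(s = grid, q_invades = inv))
  }
}

#' Largest drive cost at which the drive still fixes
#'
#' @inheritParams sib_invasion_threshold
#' @return list with `max_s` (0 if no grid point fixes).
#' @export
largest_fixing_s <- function(m, d = 1, h = 0,
                             init_drive = 0.01, init_Q = 0.01,
                             grid_step = 0.01,
                             stop = stopping_rule(1e5),
                             method = c("bisect", "scan")) {
  method <- match.arg(method)
  grid <- seq(grid_step, 1, by = grid_step)
  fixes <- function(s) {
    res <- run_sib_homing(sib_params(s, m, d, h, init_drive, init_Q), stop)
    res$outcome$allele_status[["A"]] == "fixed"
  }
  if (method == "bisect") {
    k <- bisect_largest_true(grid, fixes)
    list(max_s = if (k == 0L) 0 else grid[k])
  } else {
    ok <- vapply(grid, fixes, logical(1))
    list(max_s = if (any(ok)) grid[max(which(ok))] else 0,
         grid = data.frame(s = grid, fixed = ok))
  }
}

#' Equilibrium scan of the sib-mating homing model over drive costs
#'
#' Runs the recursion to its stopping condition for each `s` and reports the
#' equilibrium drive frequency, Q frequency, mean fitness (average female
#' survival) and the no-sib-mating reference mean fitness `1 - s` (a two-sex
#' homing drive fixes for any `s < 1` in the absence of sib mating).
#'
#' @param m sib-mating fraction.
#' @param s_values drive-cost grid.
#' @param d,h,init_drive,init_Q,stop as in [sib_invasion_threshold()].
#' @return data.frame with one row per `s`.
#' @export
scan_sib_homing <- function(m, s_values = seq(0.01, 0.99, by = 0.01),
                            d = 1, h = 0, init_drive = 0.01, init_Q = 0.01,
                            stop = stopping_rule(1e5)) {
  rows <- lapply(s_values, function(s) {
    res <- run_sib_homing(sib_params(s, m, d, h, init_drive, init_Q), stop)
    af <- final_alleles(res$trajectory)
    data.frame(s = s, drive_freq = unname(af["A"]), q_freq = unname(af["Q"]),
               mean_fitness = res$outcome$mean_fitness,
               mean_fitness_no_sib = 1 - s,
               drive_status = res$outcome$allele_status[["A"]],
               q_invaded = q_invaded(res$trajectory, init_Q))
  })
  do.call(rbind, rows)
}

#' Does unlinked type-M resistance evolve to block the drive?
#'
#' Two-locus haploid-sex comparison model: the drive locus A/a as in
#' [diploid_offspring_rule()], plus an unlinked resistance locus R/r whose
#' uppercase allele, dominant in the diploid phase and cost-free, completely
#' blocks distortion (Aa diploids carrying R segregate Mendelianly). Random
#' mating throughout.
#'
#' @param s drive homozygote cost.
#' @param d distortion when unblocked.
#' @param init_drive,init_resistance initial frequencies.
#' @param stop a [stopping_rule()].
#' @return `TRUE` if the drive fails to fix by the generation cap.
#' @export
type_m_comparison <- function(s, d = 1, init_drive = 0.01,
                              init_resistance = 0.01,
                              stop = stopping_rule(1e5)) {
  model <- family_model(c("A", "R"), function(dip) {
    a <- dip[["A"]]
    blocked <- dip[["R"]] > 0L
    list(viability = if (a == 2L) 1 - s else 1,
         components = homing_components(a, if (blocked) 0.5 else d,
                                        c(R = dip[["R"]] / 2)))
  })
  traj <- run_family(model, c(A = init_drive, R = init_resistance), stop)
  out <- outcome_summary(traj, drive_loci = "A")
  !out$resistance_free
}
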