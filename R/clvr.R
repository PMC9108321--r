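# ClvR (cleave-and-rescue) toxin-antidote drive in the haploid-sex life
# cycle. Locus C/c carries the construct: allele C converts every wild-type
# g allele in the diploid to a nonfunctional G and rescues GG from death;
# ccGG diploids die, CC diploids have fitness 1 - sigma. The unlinked Q/q
# locus enforces sib mating as in the homing model.

#' Parameters of the ClvR vs sib-mating model
#'
#' @param sigma fitness reduction of CC diploids, in `[0, 1]`.
#' @param m sib-mating fraction enforced by Q mothers.
#' @param init_C,init_Q initial allele frequencies (0.07 for the figure
#'   reproductions; set `init_Q = 0` for ClvR alone).
#' @param init_G initial frequency of the nonfunctional G allele. The
#'   default 0 is an intact wild-type background. `init_G = 1` starts from
#'   the fully converted background (the evolved-drive state in which the
#'   essential locus is fixed for the null allele), which is the state the
#'   closed-form equilibrium describes; it matters only at the degenerate
#'   boundary `sigma = 1`, where the recursion from an intact background
#'   stalls on a neutral curve of interior equilibria instead of fixing G.
#' @return object of class `clvr_params`.
#' @export
clvr_params <- function(sigma, m = 0, init_C = 0.07, init_Q = 0.07,
                        init_G = 0) {
  stopifnot(sigma >= 0, sigma <= 1, m >= 0, m <= 1,
            init_C >= 0, init_C <= 1, init_Q >= 0, init_Q <= 1,
            init_G >= 0, init_G <= 1)
  structure(list(sigma = sigma, m = m, init_C = init_C, init_Q = init_Q,
                 init_G = init_G),
            class = "clvr_params")
}

#' Conversion and fitness of a ClvR diploid
#'
#' Genotypes carrying C convert every g allele to G before gamete
#' production; viability is 0 for `ccGG`, `1 - sigma` for `CC`, and 1
#' otherwise; gametes are Mendelian after conversion.
#'
#' @param genotype diploid genotype at the C and G loci, e.g. `"Ccgg"`,
#'   `"ccGG"` (within-locus allele order ignored).
#' @param sigma CC fitness reduction.
#' @return list with `viability` and `gametes`, the probability distribution
#'   over the four `CG` haplotypes.
#' @examples
#' clvr_conversion_and_fitness("Ccgg", sigma = 0.4)  # viable; cG and CG gametes
#' clvr_conversion_and_fitness("ccGG", sigma = 0.4)  # dies: no rescue
#' @export
clvr_conversion_and_fitness <- function(genotype, sigma) {
  chars <- strsplit(genotype, "")[[1]]
  stopifnot(length(chars) == 4, all(toupper(chars) == c("C", "C", "G", "G")))
  n_C <- sum(chars[1:2] == "C")
  n_G <- sum(chars[3:4] == "G")
  rule <- clvr_rule(n_C, n_G, sigma)
  haps <- enumerate_genotypes(c("C", "G"), ploidy = 1L)
  pr <- ifelse(haps$counts[, "C"] == 1L, rule$transmit[["C"]],
               1 - rule$transmit[["C"]]) *
        ifelse(haps$counts[, "G"] == 1L, rule$transmit[["G"]],
               1 - rule$transmit[["G"]])
  list(viability = rule$viability, gametes = stats::setNames(pr, haps$labels))
}

clvr_rule <- function(n_C, n_G, sigma) {
  if (n_C > 0L) n_G <- 2L                     # g -> G conversion
  viability <- if (n_C == 0L && n_G == 2L) 0
               else if (n_C == 2L) 1 - sigma
               else 1
  list(viability = viability, transmit = c(C = n_C / 2, G = n_G / 2))
}

clvr_model <- function(params) {
  family_model(c("C", "G", "Q"), function(dip) {
    rule <- clvr_rule(dip[["C"]], dip[["G"]], params$sigma)
    list(viability = rule$viability,
         transmit = c(rule$transmit, Q = dip[["Q"]] / 2))
  }, sib_locus = "Q", m = params$m)
}

#' Run the ClvR recursion, with or without sib mating
#'
#' Without sib mating (`init_Q = 0`), ClvR evolution fixes the nonfunctional
#' G allele and leaves C at its overdominant polymorphic frequency
#' `1/(1 + sigma)`, with equilibrium mean fitness `1/(1 + sigma)`. With the
#' sib-mating allele present, Q evolves through the family machinery and can
#' purge ClvR.
#'
#' @param params a [clvr_params()].
#' @param stop a [stopping_rule()]; the default caps at 20000 generations.
#' @return list with `trajectory` and `outcome`.
#' @export
run_clvr <- function(params, stop = stopping_rule(2e4)) {
  traj <- run_family(clvr_model(params),
                     c(C = params$init_C, G = params$init_G,
                       Q = params$init_Q), stop)
  list(trajectory = traj, outcome = outcome_summary(traj, drive_loci = "C"))
}

#' Closed-form equilibrium frequency of the ClvR allele
#'
#' Equilibrium frequency of C under a fixed inbreeding coefficient `f`:
#' `(1 - f * sigma) / ((1 + sigma) * (1 - f))`; at `f = 0` this is
#' `1/(1 + sigma)`.
#'
#' @param sigma CC fitness reduction.
#' @param f inbreeding coefficient in `[0, 1)` with `f * sigma < 1`.
#' @return equilibrium frequency of C.
#' @export
clvr_equilibrium_freq <- function(sigma, f = 0) {
  stopifnot(sigma >= 0, sigma <= 1)
  if (any(f >= 1)) stop("f = 1 is outside the model (no outcrossing)")
  stopifnot(all(f >= 0), all(f * sigma < 1))
  (1 - f * sigma) / ((1 + sigma) * (1 - f))
}

# Sib mating counts as selected against ClvR when it suppresses the drive:
# ClvR is lost by the cap and Q has risen above its initial frequency. (Once
# ClvR is lost Q is neutral and need not fix, so a pure frequency-multiple
# classifier would miss these runs; outcomes are all-or-none, with Q either
# declining during unimpeded ClvR evolution or purging ClvR entirely.)
clvr_q_selected <- function(traj, init_Q, thr = 1 - 1e-8) {
  af <- final_alleles(traj)
  unname(af["C"] <= 1 - thr & af["Q"] > init_Q)
}

#' Smallest ClvR cost at which sib mating is selected
#'
#' @param m sib-mating fraction enforced by Q.
#' @param init_C,init_Q initial frequencies.
#' @param grid_step grid increment for `sigma`.
#' @param stop a [stopping_rule()].
#' @param method `"bisect"` or `"scan"`.
#' @return list with `threshold_sigma` (NA if Q never invades on the grid).
#' @export
clvr_invasion_threshold <- function(m, init_C = 0.07, init_Q = 0.07,
                                    grid_step = 0.01,
                                    stop = stopping_rule(2e4),
                                    method = c("bisect", "scan")) {
  method <- match.arg(method)
  grid <- seq(grid_step, 1, by = grid_step)
  invades <- function(sigma) {
    res <- run_clvr(clvr_params(sigma, m, init_C, init_Q), stop)
    clvr_q_selected(res$trajectory, init_Q, stop$fixation_threshold)
  }
  if (method == "bisect") {
    k <- bisect_largest_true(grid, function(sg) !invades(sg))
    list(threshold_sigma = if (k == length(grid)) NA_real_ else grid[k + 1L])
  } else {
    inv <- vapply(grid, invades, logical(1))
    list(threshold_sigma = if (any(inv)) grid[min(which(inv))] else NA_real_,
         grid = data.frame(sigma = grid, q_invades = inv))
  }
}

#' Equilibrium scan of the ClvR model over sigma
#'
#' @param m sib-mating fraction.
#' @param sigma_values grid of CC fitness reductions.
#' @param init_C,init_Q,stop as in [clvr_invasion_threshold()].
#' @return data.frame with equilibrium mean fitness with sib mating, the
#'   no-sib reference `1/(1 + sigma)`, final C and Q frequencies and the Q
#'   invasion flag for each `sigma`.
#' @export
scan_clvr <- function(m, sigma_values = seq(0.01, 0.99, by = 0.01),
                      init_C = 0.07, init_Q = 0.07,
                      stop = stopping_rule(2e4)) {
  rows <- lapply(sigma_values, function(sg) {
    res <- run_clvr(clvr_params(sg, m, init_C, init_Q), stop)
    af <- final_alleles(res$trajectory)
    data.frame(sigma = sg, mean_fitness = res$outcome$mean_fitness,
               mean_fitness_no_sib = 1 / (1 + sg),
               c_freq = unname(af["C"]), q_freq = unname(af["Q"]),
               q_invaded = clvr_q_selected(res$trajectory, init_Q,
                                           stop$fixation_threshold))
  })
  do.call(rbind, rows)
}
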