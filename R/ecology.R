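# Ecology of a male-limited homing drive with unlinked resistance: discrete
# generations, births proportional to adult females, and "ceiling" density
# dependence on offspring viability. Two loci (A/a drive, R/r resistance)
# inherit the genetics of the two-drive module's single-drive case.

#' Parameters of the ecological homing-drive model
#'
#' Offspring survival is the product of a density-independent term (1 for
#' non-AA, `1 - sb` for AA) and a ceiling density-dependent term
#' (`min(1, K/N)` for non-AA, `min(1, K(1 - sK)/N)` for AA), where `N` is
#' the number of progeny born that generation.
#'
#' @param b per-female birth rate (genotype-independent).
#' @param K ceiling threshold on progeny number.
#' @param sb density-independent viability reduction of AA offspring.
#' @param sK density-dependent viability reduction of AA offspring.
#' @param knockdown `NULL`, or `list(period = , fraction = , mode = )`:
#'   every `period` generations the progeny number is depressed, by
#'   multiplying it by `fraction` (`mode = "proportional"`, default) or by
#'   capping it at `fraction` times the initial progeny number
#'   (`mode = "reset"`).
#' @param init_N initial adult population size.
#' @param init_drive,init_resistance initial allele frequencies.
#' @param d segregation distortion (males only; R blocks it).
#' @return object of class `eco_params`.
#' @export
eco_params <- function(b, K = 1e9, sb = 0, sK = 0, knockdown = NULL,
                       init_N = 1e9, init_drive = 5e-4,
                       init_resistance = 5e-4, d = 1) {
  stopifnot(b > 0, K > 0, sb >= 0, sb <= 1, sK >= 0, sK <= 1, init_N > 0,
            init_drive >= 0, init_drive <= 1,
            init_resistance >= 0, init_resistance <= 1, d >= 0.5, d <= 1)
  if (!is.null(knockdown)) {
    if (is.null(knockdown$mode)) knockdown$mode <- "proportional"
    stopifnot(knockdown$period >= 1, knockdown$fraction > 0,
              knockdown$fraction <= 1,
              knockdown$mode %in% c("proportional", "reset"))
  }
  structure(list(b = b, K = K, sb = sb, sK = sK, knockdown = knockdown,
                 init_N = init_N, init_drive = init_drive,
                 init_resistance = init_resistance, d = d),
            class = "eco_params")
}

#' Offspring survival probability in the ecology model
#'
#' @param genotype drive-locus genotype label (`"aa"`, `"Aa"`, `"AA"`) or
#'   allele count 0..2; only AA suffers the viability reductions.
#' @param N number of progeny born in the population this generation.
#' @param params an [eco_params()].
#' @return survival probability in `[0, 1]` (1 when `N = 0`).
#' @export
offspring_viability <- function(genotype, N, params) {
  count <- if (is.numeric(genotype)) genotype
           else sum(strsplit(genotype, "")[[1]] == "A")
  stopifnot(count %in% 0:2, N >= 0)
  if (N == 0) return(1)
  if (count == 2L)
    (1 - params$sb) * min(1, params$K * (1 - params$sK) / N)
  else
    min(1, params$K / N)
}

eco_genetics <- function(d) {
  table <- enumerate_genotypes(c("A", "R"))
  transmit_m <- table$counts / 2
  het <- table$counts[, "A"] == 1L & table$counts[, "R"] == 0L
  transmit_m[het, "A"] <- d
  list(table = table,
       Gm = gamete_matrix(table, transmit_m),
       Gf = gamete_matrix(table, table$counts / 2),
       M = zygote_matrix(table))
}

#' Run the ecological homing-drive model
#'
#' Each generation: progeny born `N = b x` (adult females, half the adult
#' population); optional knockdown depresses `N`; offspring genotypes follow
#' random mating with male-limited homing and dominant cost-free blocking
#' resistance; offspring of both sexes survive per [offspring_viability()];
#' survivors are the next generation's adults. The population is flagged
#' extinct when it falls below one adult.
#'
#' @param params an [eco_params()].
#' @param stop a [stopping_rule()]; default caps at 5000 generations.
#' @param stop_at_extinction if `TRUE` (default) the run halts once the
#'   population falls below one adult. Set to `FALSE` to let the
#'   deterministic allele-frequency dynamics continue on the (vanishing)
#'   population masses — used by the resistance-free scans, where the
#'   allele race is the question and the census extinction threshold is a
#'   classification convention, not dynamics.
#' @return a `drive_trajectory` data.frame with columns `generation`, `A`,
#'   `R`, `mean_fitness` (realized mean offspring survival relative to
#'   non-AA survival), `population_size` (adults) and `relative_density`
#'   (adults / K); attributes `extinct` and `extinction_generation`.
#' @export
run_ecology <- function(params, stop = stopping_rule(5000),
                        stop_at_extinction = TRUE) {
  gen_mach <- eco_genetics(params$d)
  table <- gen_mach$table
  freq <- hardy_weinberg_state(table, c(A = params$init_drive,
                                        R = params$init_resistance))
  adults <- params$init_N
  init_progeny <- params$b * params$init_N / 2
  n_rec <- stop$max_generations + 1L
  rec <- matrix(NA_real_, n_rec, 5,
                dimnames = list(NULL, c("A", "R", "mean_fitness",
                                        "population_size", "relative_density")))
  rec[1L, ] <- c(allele_frequencies(freq, table), 1, adults, adults / params$K)
  gen <- 0L; k <- 1L
  extinct <- FALSE; extinction_generation <- NA_integer_
  converged <- FALSE
  is_AA <- table$counts[, "A"] == 2L
  while (gen < stop$max_generations && !(extinct && stop_at_extinction)) {
    N <- params$b * adults / 2
    kd <- params$knockdown
    if (!is.null(kd) && gen %% kd$period == 0L && gen > 0L) {
      N <- if (kd$mode == "proportional") N * kd$fraction
           else min(N, kd$fraction * init_progeny)
    }
    gf <- drop(crossprod(gen_mach$Gf, freq)); gf <- gf / sum(gf)
    gm <- drop(crossprod(gen_mach$Gm, freq)); gm <- gm / sum(gm)
    off <- drop(gen_mach$M %*% kronecker(gf, gm))
    surv_AA <- (1 - params$sb) * min(1, params$K * (1 - params$sK) / N)
    surv_other <- min(1, params$K / N)
    surv <- ifelse(is_AA, surv_AA, surv_other)
    counts_next <- N * off * surv
    prev_adults <- adults
    adults <- sum(counts_next)
    gen <- gen + 1L; k <- k + 1L
    if (adults < 1 && !extinct) {
      extinct <- TRUE
      extinction_generation <- gen
    }
    if (adults <= 1e-200) {           # mass underflow guard
      rec[k, ] <- c(allele_frequencies(off, table),
                    sum(off * surv) / surv_other, adults, adults / params$K)
      break
    }
    if (extinct && stop_at_extinction) {
      rec[k, ] <- c(allele_frequencies(off, table),
                    sum(off * surv) / surv_other, adults, adults / params$K)
      break
    }
    new_freq <- counts_next / adults
    delta <- max(abs(new_freq - freq))
    adults_settled <- abs(adults - prev_adults) <= stop$delta_tolerance * prev_adults
    rec[k, ] <- c(allele_frequencies(freq <- new_freq, table),
                  sum(off * surv) / surv_other, adults, adults / params$K)
    if (delta < stop$delta_tolerance && is.null(kd) &&
        (adults_settled || !stop_at_extinction)) {
      converged <- TRUE
      break
    }
  }
  traj <- data.frame(generation = 0:gen, rec[seq_len(k), , drop = FALSE])
  structure(traj, class = c("drive_trajectory", "data.frame"),
            final = list(freq = freq, generation = gen, adults = adults),
            converged = converged, stop = stop,
            extinct = extinct, extinction_generation = extinction_generation)
}

#' Resistance-free upper limit of the ecological viability coefficient
#'
#' Grid-scans the active viability coefficient (`sb` in density-independent
#' mode, `sK` in density-dependent mode) and returns the largest value for
#' which the drive allele fixes by the generation cap. Fixation is monotone
#' in the coefficient, so the default search bisects over the grid.
#'
#' @param mode `"DI"` (drive affects density-independent viability) or
#'   `"DD"` (density-dependent).
#' @param b per-female birth rate.
#' @param knockdown as in [eco_params()].
#' @param grid_step coefficient increment.
#' @param stop a [stopping_rule()].
#' @param method `"bisect"` or `"scan"`.
#' @param ... passed to [eco_params()] (e.g. `K`, initial frequencies).
#' @return list with `max_coefficient` (0 if no grid point fixes).
#' @export
max_resistance_free_eco <- function(mode = c("DI", "DD"), b = 3,
                                    knockdown = NULL, grid_step = 0.01,
                                    stop = stopping_rule(5000),
                                    method = c("bisect", "scan"), ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  fixes <- function(s) {
    params <- if (mode == "DI")
      eco_params(b = b, sb = s, sK = 0, knockdown = knockdown, ...)
    else
      eco_params(b = b, sb = 0, sK = s, knockdown = knockdown, ...)
    traj <- run_ecology(params, stop, stop_at_extinction = FALSE)
    unname(final_alleles(traj)["A"] >= stop$fixation_threshold)
  }
  if (method == "bisect") {
    k <- bisect_largest_true(grid, fixes)
    list(max_coefficient = if (k == 0L) 0 else grid[k])
  } else {
    ok <- vapply(grid, fixes, logical(1))
    list(max_coefficient = if (any(ok)) grid[max(which(ok))] else 0,
         grid = data.frame(coefficient = grid, fixed = ok))
  }
}

#' Classify long-run persistence of the population
#'
#' @param params an [eco_params()].
#' @param stop a [stopping_rule()].
#' @return list with `outcome` (`"extinct"` or `"persists"`), the extinction
#'   generation (if extinct) or the final density relative to `K`, and the
#'   trajectory.
#' @export
classify_persistence <- function(params, stop = stopping_rule(5000)) {
  traj <- run_ecology(params, stop)
  if (isTRUE(attr(traj, "extinct")))
    list(outcome = "extinct",
         generation = attr(traj, "extinction_generation"),
         trajectory = traj)
  else
    list(outcome = "persists",
         relative_density = traj$relative_density[nrow(traj)],
         trajectory = traj)
}
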