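#' Stopping rule for deterministic recursions
#'
#' Deterministic recursions approach boundaries asymptotically, so runs are
#' terminated either at a generation cap, or when the largest per-genotype
#' frequency change in one generation falls below `delta_tolerance`. An
#' allele is declared fixed when its frequency reaches `fixation_threshold`
#' and lost when it falls to `1 - fixation_threshold`.
#'
#' @param max_generations maximum number of generations to iterate (>= 1).
#' @param fixation_threshold frequency at which an allele counts as fixed.
#' @param delta_tolerance per-generation frequency-change convergence bound.
#' @return object of class `stopping_rule`.
#' @export
stopping_rule <- function(max_generations,
                          fixation_threshold = 1 - 1e-8,
                          delta_tolerance = 1e-13) {
  stopifnot(max_generations >= 1,
            fixation_threshold > 0, fixation_threshold < 1,
            delta_tolerance >= 0)
  structure(list(max_generations = as.integer(max_generations),
                 fixation_threshold = fixation_threshold,
                 delta_tolerance = delta_tolerance),
            class = "stopping_rule")
}

# Gamete-distribution matrix for a diploid genotype table.
#
# transmit: n_genotype x n_locus matrix; entry [i, l] is the probability that
# genotype i transmits the uppercase allele at locus l. Loci are unlinked, so
# a gamete haplotype's probability is the product over loci. Returns the
# n_genotype x n_haplotype matrix G with rows summing to 1.
gamete_matrix <- function(table, transmit) {
  haps <- enumerate_genotypes(table$loci, ploidy = 1L)
  G <- matrix(1, table$n, haps$n)
  for (l in seq_along(table$loci)) {
    h <- haps$counts[, l]
    G <- G * t(vapply(seq_len(table$n),
                      function(i) ifelse(h == 1L, transmit[i, l], 1 - transmit[i, l]),
                      numeric(haps$n)))
  }
  G
}

# Map from (female haplotype, male haplotype) pairs to offspring genotype
# rows: a n_genotype x n_hap^2 0/1 matrix; column order matches
# kronecker(g_female, g_male) (female index major).
zygote_matrix <- function(table) {
  haps <- enumerate_genotypes(table$loci, ploidy = 1L)
  n_h <- haps$n
  M <- matrix(0, table$n, n_h * n_h)
  for (jf in seq_len(n_h)) {
    for (jm in seq_len(n_h)) {
      g <- genotype_row(table, haps$counts[jf, ] + haps$counts[jm, ])
      M[g, (jf - 1L) * n_h + jm] <- 1
    }
  }
  M
}

#' Build a diploid random-mating model
#'
#' Assembles the exhaustive-enumeration machinery for a deterministic
#' discrete-generation recursion with two sexes: sex-specific
#' gamete-production rules (segregation distortion, homing, conversion) and
#' sex-specific fitnesses. Offspring genotype frequencies are the random
#' union of the female and male gamete pools, each pool being the
#' fitness-weighted sum of parental gamete distributions. Because selection
#' weights gamete contribution, "fertility selection on adults" and
#' "viability selection before mating" are the same operation in this
#' discrete-generation life cycle.
#'
#' @param table a diploid [genotype_table][enumerate_genotypes].
#' @param transmit_female,transmit_male `n x L` matrices of per-locus
#'   probabilities of transmitting the uppercase allele (rows = genotypes).
#' @param fitness_female,fitness_male length-`n` viability/fertility weights
#'   in `[0, 1]`.
#' @return object of class `diploid_model`.
#' @export
diploid_model <- function(table, transmit_female, transmit_male,
                          fitness_female = rep(1, table$n),
                          fitness_male = rep(1, table$n)) {
  stopifnot(all(table$ploidy == 2L),
            all(fitness_female >= 0), all(fitness_female <= 1),
            all(fitness_male >= 0), all(fitness_male <= 1))
  structure(list(
    table = table,
    Gf = gamete_matrix(table, transmit_female),
    Gm = gamete_matrix(table, transmit_male),
    M = zygote_matrix(table),
    wf = fitness_female,
    wm = fitness_male), class = "diploid_model")
}

#' One generation of a diploid random-mating recursion
#'
#' Advances a normalized genotype-frequency state by one generation:
#' fitness-weighted gamete pools are formed per sex, offspring are the random
#' union of the two pools (equivalent to summing over all mother x father x
#' gamete x gamete combinations), and the result is renormalized. The same
#' offspring distribution applies to both sexes, so a single census vector
#' suffices.
#'
#' @param state list with `freq` (genotype frequencies summing to 1) and
#'   `generation`.
#' @param model a [diploid_model()].
#' @return a state list with updated `freq` and incremented `generation`.
#' @export
next_generation <- function(state, model) {
  ff <- state$freq * model$wf
  fm <- state$freq * model$wm
  sf <- sum(ff); sm <- sum(fm)
  if (sf <= 0 || sm <= 0)
    stop("population inviable: zero post-selection mass at generation ",
         state$generation, call. = FALSE)
  gf <- drop(crossprod(model$Gf, ff)) / sf
  gm <- drop(crossprod(model$Gm, fm)) / sm
  off <- drop(model$M %*% kronecker(gf, gm))
  list(freq = off / sum(off), generation = state$generation + 1L)
}

#' Iterate a diploid model to a stopping condition
#'
#' Applies [next_generation()] until the generation cap is reached or the
#' maximum absolute per-genotype frequency change drops below the stopping
#' rule's `delta_tolerance`. Per-generation allele frequencies and mean
#' fitness (census frequencies weighted by female fitness) are recorded.
#'
#' @param freq initial genotype-frequency vector (will be normalized).
#' @param model a [diploid_model()].
#' @param stop a [stopping_rule()].
#' @param on_generation optional hook `function(state) state`, applied after
#'   each generation (used e.g. for sequential drive introduction).
#' @return a `drive_trajectory`: data.frame with columns `generation`, one
#'   allele-frequency column per locus, and `mean_fitness`; the final state
#'   and convergence flag are attached as attributes.
#' @export
iterate <- function(freq, model, stop, on_generation = NULL) {
  table <- model$table
  state <- list(freq = freq / sum(freq), generation = 0L)
  n_rec <- stop$max_generations + 1L
  gens <- integer(n_rec)
  afs <- matrix(NA_real_, n_rec, length(table$loci),
                dimnames = list(NULL, table$loci))
  mfit <- numeric(n_rec)
  record <- function(k, st) {
    gens[k] <<- st$generation
    afs[k, ] <<- allele_frequencies(st$freq, table)
    mfit[k] <<- sum(st$freq * model$wf)
  }
  record(1L, state)
  k <- 1L
  converged <- FALSE
  while (state$generation < stop$max_generations) {
    new <- next_generation(state, model)
    if (!is.null(on_generation)) new <- on_generation(new)
    k <- k + 1L
    record(k, new)
    delta <- max(abs(new$freq - state$freq))
    state <- new
    if (delta < stop$delta_tolerance) { converged <- TRUE; break }
  }
  traj <- data.frame(generation = gens[seq_len(k)], afs[seq_len(k), , drop = FALSE],
                     mean_fitness = mfit[seq_len(k)])
  structure(traj, class = c("drive_trajectory", "data.frame"),
            final = state, converged = converged, stop = stop)
}

#' @export
print.drive_trajectory <- function(x, ...) {
  fin <- attr(x, "final")
  cat(sprintf("drive_trajectory: %d generations (%s)\n",
              max(x$generation),
              if (isTRUE(attr(x, "converged"))) "converged" else "generation cap"))
  last <- x[nrow(x), , drop = FALSE]
  cat("final: ", paste(sprintf("%s = %.6g", names(last), as.numeric(last)),
                       collapse = ", "), "\n")
  invisible(x)
}

# final allele frequencies of a trajectory
final_alleles <- function(traj) {
  loci <- setdiff(names(traj), c("generation", "mean_fitness", "population_size",
                                 "relative_density"))
  unlist(traj[nrow(traj), loci, drop = FALSE])
}

#' Summarize the outcome of a model run
#'
#' Classifies each tracked allele as fixed, lost or polymorphic at the end of
#' a run, using the stopping rule's fixation threshold.
#'
#' @param traj a `drive_trajectory` as returned by [iterate()] and the model
#'   runners.
#' @param drive_loci labels of the loci whose joint fixation defines a
#'   "resistance-free" outcome (`NULL` to skip that classification).
#' @return object of class `outcome_summary`.
#' @export
outcome_summary <- function(traj, drive_loci = NULL) {
  stop <- attr(traj, "stop")
  thr <- if (is.null(stop)) 1 - 1e-8 else stop$fixation_threshold
  af <- final_alleles(traj)
  status <- ifelse(af >= thr, "fixed", ifelse(af <= 1 - thr, "lost", "polymorphic"))
  res <- structure(list(
    allele_status = status,
    final_frequencies = af,
    mean_fitness = traj$mean_fitness[nrow(traj)],
    generations = max(traj$generation),
    converged = isTRUE(attr(traj, "converged"))),
    class = "outcome_summary")
  if (!is.null(drive_loci))
    res$resistance_free <- all(status[drive_loci] == "fixed")
  res
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("outcome_summary after", x$generations, "generations:\n")
  for (l in names(x$allele_status))
    cat(sprintf("  %s: %s (freq %.6g)\n", l, x$allele_status[l],
                x$final_frequencies[l]))
  cat(sprintf("  mean fitness %.6g\n", x$mean_fitness))
  if (!is.null(x$resistance_free))
    cat("  resistance-free:", x$resistance_free, "\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj a `drive_trajectory`.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an outcome summary as JSON
#'
#' @param outcome an [outcome_summary()].
#' @param path output file path.
#' @export
write_outcome_json <- function(outcome, path) {
  jsonlite::write_json(unclass(outcome), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
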