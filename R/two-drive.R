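# Three unlinked diploid loci: A/a and B/b are male-limited homing drives,
# R/r is a dominant, cost-free mechanistic (type-M) resistance allele that
# completely blocks distortion at both drive loci.

two_drive_table <- function() enumerate_genotypes(c("A", "B", "R"))

#' Parameters of the two-homing-drive vs resistance model
#'
#' @param s1,s2 homozygote fitness reductions of drive A and drive B, in
#'   `[0, 1]`; `s2 = NULL` for a single-drive model. The combined suppression
#'   is `1 - (1 - s1)(1 - s2)` (fitnesses are multiplicative over loci).
#' @param d segregation distortion: fraction of drive gametes produced by a
#'   drive heterozygote male with no resistance allele; 1 is perfect drive,
#'   0.5 Mendelian.
#' @param h heterozygote fitness reduction, applied per heterozygous drive
#'   locus (multiplicative over loci).
#' @param sex_of_effect `"both"` or `"females_only"`: which sexes express the
#'   drive fitness effects. Resistance is cost-free in all cases.
#' @param introduction `"single"`, `"simultaneous"` or `"sequential"`;
#'   sequential introduces drive B once drive A reaches
#'   `sequential_trigger`.
#' @param sequential_trigger drive-A frequency that triggers introduction of
#'   drive B.
#' @param init_drive initial frequency of each introduced drive allele.
#' @param init_resistance initial frequency of the resistance allele.
#' @return object of class `drive_params`.
#' @export
drive_params <- function(s1, s2 = NULL, d = 1, h = 0,
                         sex_of_effect = c("both", "females_only"),
                         introduction = c("single", "simultaneous", "sequential"),
                         sequential_trigger = 0.9995,
                         init_drive = if (is.null(s2)) 0.01 else 0.005,
                         init_resistance = 0.005) {
  sex_of_effect <- match.arg(sex_of_effect)
  introduction <- match.arg(introduction)
  if (is.null(s2) && introduction != "single")
    stop("two drive effects are required for ", introduction, " introduction")
  if (!is.null(s2) && introduction == "single")
    introduction <- "simultaneous"
  stopifnot(s1 >= 0, s1 <= 1, is.null(s2) || (s2 >= 0 && s2 <= 1),
            d >= 0.5, d <= 1, h >= 0, h <= 1,
            init_drive > 0, init_drive < 1,
            init_resistance >= 0, init_resistance < 1,
            sequential_trigger > 0, sequential_trigger < 1)
  structure(list(s1 = s1, s2 = s2, d = d, h = h,
                 sex_of_effect = sex_of_effect, introduction = introduction,
                 sequential_trigger = sequential_trigger,
                 init_drive = init_drive, init_resistance = init_resistance),
            class = "drive_params")
}

# per-locus transmission probabilities for the 27 genotypes
two_drive_transmit <- function(table, d, male) {
  P <- table$counts / 2
  if (male) {
    no_res <- table$counts[, "R"] == 0L
    for (locus in c("A", "B")) {
      het <- table$counts[, locus] == 1L
      P[het & no_res, locus] <- d
    }
  }
  P
}

#' Male gamete distribution in the two-drive model
#'
#' Homing operates in males only: a male heterozygous at a drive locus and
#' carrying no resistance allele transmits the drive allele with probability
#' `d`, independently at each drive locus. Any genotype with at least one R
#' allele — and every locus in females — segregates Mendelianly.
#'
#' @param genotype genotype label, e.g. `"AaBbrr"` (allele order within a
#'   locus is ignored).
#' @param d segregation distortion in `[0.5, 1]`.
#' @return named numeric vector of probabilities over the 8 gamete
#'   haplotypes.
#' @examples
#' male_gamete_distribution("AaBbrr", d = 1)    # all mass on ABr
#' male_gamete_distribution("AaBbRr", d = 1)    # Mendelian: 1/8 each
#' @export
male_gamete_distribution <- function(genotype, d = 1) {
  table <- two_drive_table()
  i <- match_genotype(table, genotype)
  G <- gamete_matrix(table, two_drive_transmit(table, d, male = TRUE))
  stats::setNames(G[i, ], enumerate_genotypes(table$loci, 1L)$labels)
}

# resolve a genotype label irrespective of within-locus allele order
match_genotype <- function(table, genotype) {
  i <- table$index[genotype]
  if (!is.na(i)) return(unname(i))
  chars <- strsplit(genotype, "")[[1]]
  if (length(chars) != sum(table$ploidy)) stop("bad genotype label: ", genotype)
  counts <- integer(length(table$loci))
  k <- 0L
  for (l in seq_along(table$loci)) {
    seg <- chars[k + seq_len(table$ploidy[l])]
    if (!all(toupper(seg) == toupper(table$loci[l])))
      stop("bad genotype label: ", genotype)
    counts[l] <- sum(seg == toupper(table$loci[l]))
    k <- k + table$ploidy[l]
  }
  genotype_row(table, counts)
}

#' Genotype fitness in the two-drive model
#'
#' Fitnesses are multiplicative over loci: each drive locus contributes
#' `1 - s_i` for the drive homozygote, `1 - h` for the heterozygote and 1
#' for the wild-type homozygote; the resistance locus is cost-free. The
#' effect is expressed only in the sexes given by `sex_of_effect`.
#'
#' @param genotype genotype label, e.g. `"AABBrr"`.
#' @param params a [drive_params()].
#' @param sex `"female"` or `"male"`.
#' @return fitness in `[0, 1]`.
#' @export
genotype_fitness <- function(genotype, params, sex = c("female", "male")) {
  sex <- match.arg(sex)
  table <- two_drive_table()
  w <- two_drive_fitness(table, params, sex)
  w[match_genotype(table, genotype)]
}

two_drive_fitness <- function(table, params, sex) {
  if (sex == "male" && params$sex_of_effect == "females_only")
    return(rep(1, table$n))
  s2 <- if (is.null(params$s2)) 0 else params$s2
  fac <- function(counts, s) ifelse(counts == 2L, 1 - s,
                                    ifelse(counts == 1L, 1 - params$h, 1))
  fac(table$counts[, "A"], params$s1) * fac(table$counts[, "B"], s2)
}

two_drive_model <- function(params) {
  table <- two_drive_table()
  diploid_model(table,
                transmit_female = two_drive_transmit(table, params$d, male = FALSE),
                transmit_male = two_drive_transmit(table, params$d, male = TRUE),
                fitness_female = two_drive_fitness(table, params, "female"),
                fitness_male = two_drive_fitness(table, params, "male"))
}

# Introduce an allele at Hardy-Weinberg proportions at a locus that is
# currently monomorphic wild type: every individual's genotype at that locus
# is replaced by a Hardy-Weinberg draw at frequency p, independent of the
# rest of the genome (so a mass of wild-type homozygotes is replaced by
# carriers).
inject_locus_hw <- function(freq, table, locus, p) {
  l <- match(locus, table$loci)
  if (any(freq[table$counts[, l] > 0L] > 1e-12))
    stop("locus ", locus, " is already polymorphic")
  hw <- stats::dbinom(0:2, 2, p)
  out <- numeric(table$n)
  base <- which(table$counts[, l] == 0L)
  for (add in 0:2) {
    target <- vapply(base, function(i) {
      cnt <- table$counts[i, ]
      cnt[l] <- add
      genotype_row(table, cnt)
    }, integer(1))
    out[target] <- out[target] + freq[base] * hw[add + 1L]
  }
  out
}

#' Run the two-drive vs resistance recursion
#'
#' Random union of the sexes with male-limited homing and dominant cost-free
#' resistance; fitness effects weight adult gamete contribution. Initial
#' genotype frequencies are Hardy-Weinberg products over loci. In sequential
#' mode, drive B is injected (at `init_drive`, Hardy-Weinberg, replacing
#' wild-type homozygotes) in the first generation at which drive A reaches
#' `sequential_trigger`.
#'
#' @param params a [drive_params()].
#' @param stop a [stopping_rule()]; default caps at 1e4 generations.
#' @return list with `trajectory` (a `drive_trajectory`) and `outcome` (an
#'   [outcome_summary()]; `outcome$resistance_free` is `TRUE` when every
#'   introduced drive allele fixed within the cap).
#' @export
run_two_drive <- function(params, stop = stopping_rule(1e4)) {
  table <- two_drive_table()
  model <- two_drive_model(params)
  p0 <- c(A = params$init_drive,
          B = if (params$introduction == "simultaneous") params$init_drive else 0,
          R = params$init_resistance)
  freq <- hardy_weinberg_state(table, p0)
  injected <- params$introduction != "sequential"
  hook <- NULL
  if (!injected) {
    hook <- function(state) {
      if (!injected &&
          allele_frequencies(state$freq, table)["A"] >= params$sequential_trigger) {
        state$freq <- inject_locus_hw(state$freq, table, "B", params$init_drive)
        injected <<- TRUE
      }
      state
    }
  }
  traj <- iterate(freq, model, stop, on_generation = hook)
  drive_loci <- if (is.null(params$s2) && params$introduction == "single") "A" else c("A", "B")
  out <- outcome_summary(traj, drive_loci = drive_loci)
  out$drives_introduced <- if (injected) drive_loci else "A"
  out$resistance_free <- out$resistance_free && injected
  list(trajectory = traj, outcome = out)
}

# largest index of grid for which predicate is TRUE, assuming the predicate
# is monotone TRUE..TRUE FALSE..FALSE over the grid; returns 0 if none.
bisect_largest_true <- function(grid, predicate) {
  lo <- 0L                      # largest index known TRUE (0 = none yet)
  hi <- length(grid) + 1L       # smallest index known FALSE
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (predicate(grid[mid])) lo <- mid else hi <- mid
  }
  lo
}

#' Maximum resistance-free suppression of one or two homing drives
#'
#' Scans the combined suppression `s = 1 - (1 - s1)(1 - s2)` on a grid of
#' step `grid_step` (with equal per-drive effects `s_i = 1 - sqrt(1 - s)`
#' when two drives are introduced) and returns the largest combined `s` for
#' which every introduced drive fixes in the presence of the resistance
#' allele. Fixation is monotone (non-increasing) in `s`, so the default
#' search bisects over the grid; the exhaustive `"scan"` method evaluates
#' every grid point and is used to verify the monotone boundary.
#'
#' @param drives 1 or 2.
#' @param sex_of_effect `"both"` or `"females_only"`.
#' @param init_resistance initial resistance-allele frequency.
#' @param d segregation distortion.
#' @param h heterozygote fitness reduction.
#' @param grid_step combined-suppression increment.
#' @param introduction introduction mode for two drives (`"sequential"` or
#'   `"simultaneous"`).
#' @param init_drive initial frequency of each drive allele.
#' @param stop a [stopping_rule()].
#' @param method `"bisect"` (default) or `"scan"`.
#' @return list with `max_s` (combined suppression; 0 if no grid point
#'   fixes), `per_drive_s`, and for the scan method the full `grid`
#'   data.frame.
#' @export
max_resistance_free_s <- function(drives = 1,
                                  sex_of_effect = c("both", "females_only"),
                                  init_resistance = 0.005,
                                  d = 1, h = 0, grid_step = 0.01,
                                  introduction = c("sequential", "simultaneous"),
                                  init_drive = if (drives == 2) 0.005 else 0.01,
                                  stop = stopping_rule(1e4),
                                  method = c("bisect", "scan")) {
  sex_of_effect <- match.arg(sex_of_effect)
  introduction <- match.arg(introduction)
  method <- match.arg(method)
  stopifnot(drives %in% c(1, 2), grid_step > 0)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  per_drive <- function(s) if (drives == 2) 1 - sqrt(1 - s) else s
  fixes <- function(s) {
    s_per <- per_drive(s)
    params <- if (drives == 2)
      drive_params(s_per, s_per, d = d, h = h, sex_of_effect = sex_of_effect,
                   introduction = introduction, init_drive = init_drive,
                   init_resistance = init_resistance)
    else
      drive_params(s_per, d = d, h = h, sex_of_effect = sex_of_effect,
                   init_drive = init_drive, init_resistance = init_resistance)
    run_two_drive(params, stop)$outcome$resistance_free
  }
  if (method == "bisect") {
    k <- bisect_largest_true(grid, fixes)
    list(max_s = if (k == 0L) 0 else grid[k],
         per_drive_s = if (k == 0L) 0 else per_drive(grid[k]))
  } else {
    ok <- vapply(grid, fixes, logical(1))
    k <- if (any(ok)) max(which(ok)) else 0L
    list(max_s = if (k == 0L) 0 else grid[k],
         per_drive_s = if (k == 0L) 0 else per_drive(grid[k]),
         grid = data.frame(combined_s = grid, per_drive_s = per_drive(grid),
                           fixed = ok))
  }
}
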