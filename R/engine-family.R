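# Haploid-sex family engine.
#
# Life cycle: haploid females and males pair into "families"; each family is
# the ordered pair (maternal haplotype, paternal haplotype) and determines a
# single diploid genotype in which segregation distortion / allelic
# conversion and viability effects act. The diploid releases haploid progeny
# (sex ratio 1:1, loci unlinked). Mothers carrying the sib-mating allele
# force a fraction m of their progeny to mate within the family: sib-mated
# daughters pair with brothers drawn from the same family's progeny pool,
# and those brothers are removed from the random pool (equal male and female
# mass leaves the family). All remaining progeny join the random pools, from
# which the rest of the next generation's families are formed by random
# union.
#
# A family's progeny haplotype distribution may be a mixture over germline
# states (e.g. homing modelled as a conversion event: with probability
# 2d - 1 the heterozygous germline is converted and yields only drive
# gametes, otherwise it segregates Mendelianly, for a marginal drive-gamete
# fraction d). The mixture is invisible to random mating, which only sees
# the marginal, but it correlates the gametes of sibs and therefore matters
# for sib-mated pairs.

#' Build a haploid-sex family model
#'
#' @param loci single-letter locus labels of the haploid genome.
#' @param offspring_rule function taking a named integer vector of diploid
#'   uppercase-allele counts (0, 1 or 2 per locus) and returning
#'   `list(viability = , transmit = )` for a deterministic germline, or
#'   `list(viability = , components = list(list(weight = , transmit = ), ...))`
#'   for a mixture over germline states; `transmit` is the per-locus
#'   probability that a haploid progeny carries the uppercase allele.
#' @param sib_locus label of the locus whose uppercase allele, carried by the
#'   mother, enforces sib mating (`NULL` for pure random mating).
#' @param m fraction of a sib-mating mother's progeny that sib mate.
#' @return object of class `family_model` with precomputed per-family
#'   viabilities, marginal progeny haplotype distributions, per-component
#'   distributions for sib mating, and maternal sib-mating indicators.
#' @export
family_model <- function(loci, offspring_rule, sib_locus = NULL, m = 0) {
  stopifnot(m >= 0, m <= 1)
  haps <- enumerate_genotypes(loci, ploidy = 1L)
  n_h <- haps$n
  n_fam <- n_h * n_h
  # family index k = (mother - 1) * n_h + father
  v <- numeric(n_fam)
  H <- matrix(0, n_fam, n_h)          # marginal progeny distribution
  q_mother <- logical(n_fam)
  comp_fam <- integer(0)              # component row -> family
  comp_w <- numeric(0)                # component weight within family
  Hc <- NULL                          # per-component progeny distributions
  sib_col <- if (is.null(sib_locus)) 0L else match(sib_locus, loci)
  if (!is.null(sib_locus) && is.na(sib_col)) stop("unknown sib locus")
  hap_dist <- function(transmit) {
    pr <- rep(1, n_h)
    for (l in seq_along(loci)) {
      h <- haps$counts[, l]
      pr <- pr * ifelse(h == 1L, transmit[l], 1 - transmit[l])
    }
    pr
  }
  comp_rows <- list()
  for (i in seq_len(n_h)) {
    for (j in seq_len(n_h)) {
      k <- (i - 1L) * n_h + j
      dip <- haps$counts[i, ] + haps$counts[j, ]
      names(dip) <- loci
      rule <- offspring_rule(dip)
      stopifnot(rule$viability >= 0, rule$viability <= 1)
      comps <- if (!is.null(rule$components)) rule$components
               else list(list(weight = 1, transmit = rule$transmit))
      wsum <- sum(vapply(comps, `[[`, numeric(1), "weight"))
      stopifnot(abs(wsum - 1) < 1e-12)
      v[k] <- rule$viability
      for (cm in comps) {
        stopifnot(all(cm$transmit >= 0), all(cm$transmit <= 1))
        pr <- hap_dist(cm$transmit)
        H[k, ] <- H[k, ] + cm$weight * pr
        comp_rows[[length(comp_rows) + 1L]] <- list(k = k, w = cm$weight, pr = pr)
      }
      q_mother[k] <- sib_col > 0L && haps$counts[i, sib_col] == 1L
    }
  }
  comp_fam <- vapply(comp_rows, `[[`, integer(1), "k")
  comp_w <- vapply(comp_rows, `[[`, numeric(1), "w")
  Hc <- do.call(rbind, lapply(comp_rows, `[[`, "pr"))
  structure(list(loci = loci, haps = haps, n_hap = n_h, n_fam = n_fam,
                 v = v, H = H, Hc = Hc, comp_fam = comp_fam, comp_w = comp_w,
                 q_mother = q_mother, m = m, sib_locus = sib_locus),
            class = "family_model")
}

#' One generation of the sib-mating family recursion
#'
#' @param F_freq normalized family-frequency vector (mother-haplotype major).
#' @param model a [family_model()].
#' @return list with the next normalized family frequencies `F_freq`, the
#'   cohort `mean_fitness` (average progeny survival, equal to average female
#'   survival since the sexes are produced 1:1), and `pool` (the haplotype
#'   distribution of surviving progeny, used for allele-frequency tracking).
#' @export
next_generation_family <- function(F_freq, model) {
  W <- F_freq * model$v               # surviving progeny mass per family
  total <- sum(W)
  if (total <= 0)
    stop("population inviable: no surviving progeny", call. = FALSE)
  mean_fitness <- total / sum(F_freq)
  sib <- model$m * W * model$q_mother # mass sib-mated within each family
  rand <- W - sib                     # mass joining the random pools
  # sib pairs: daughter and son drawn from the same germline component
  sib_rows <- sib[model$comp_fam] * model$comp_w
  F_sib <- crossprod(model$Hc * sib_rows, model$Hc)  # mother x father
  pool <- drop(crossprod(model$H, rand))             # same for both sexes
  s_pool <- sum(pool)
  F_rand <- if (s_pool > 0) outer(pool, pool) / s_pool else 0 * F_sib
  F_new <- as.vector(t(F_sib + F_rand))   # k = (mother-1)*n_hap + father
  all_pool <- drop(crossprod(model$H, W))
  list(F_freq = F_new / sum(F_new), mean_fitness = mean_fitness,
       pool = all_pool / sum(all_pool))
}

#' Iterate a haploid-sex family model
#'
#' Starts from linkage equilibrium at the given allele frequencies (random
#' mating: initial families are the outer product of the haplotype pool with
#' itself) and iterates [next_generation_family()] under a
#' [stopping_rule()]. Allele frequencies are reported in the surviving
#' progeny pool; mean fitness is average progeny (female) survival.
#'
#' @param model a [family_model()].
#' @param init named per-locus initial frequencies of the uppercase alleles.
#' @param stop a [stopping_rule()].
#' @return a `drive_trajectory` data.frame (see [iterate()]).
#' @export
run_family <- function(model, init, stop) {
  haps <- model$haps
  hf <- rep(1, model$n_hap)
  init <- init[model$loci]
  for (l in seq_along(model$loci)) {
    h <- haps$counts[, l]
    hf <- hf * ifelse(h == 1L, init[l], 1 - init[l])
  }
  F_freq <- as.vector(t(outer(hf, hf)))
  n_rec <- stop$max_generations + 1L
  afs <- matrix(NA_real_, n_rec, length(model$loci),
                dimnames = list(NULL, model$loci))
  mfit <- numeric(n_rec)
  afs[1L, ] <- init
  mfit[1L] <- sum(F_freq * model$v)
  k <- 1L
  gen <- 0L
  converged <- FALSE
  counts <- haps$counts
  while (gen < stop$max_generations) {
    res <- next_generation_family(F_freq, model)
    gen <- gen + 1L
    k <- k + 1L
    afs[k, ] <- drop(crossprod(counts, res$pool))
    mfit[k] <- res$mean_fitness
    delta <- max(abs(res$F_freq - F_freq))
    F_freq <- res$F_freq
    if (delta < stop$delta_tolerance) { converged <- TRUE; break }
  }
  traj <- data.frame(generation = 0:gen, afs[seq_len(k), , drop = FALSE],
                     mean_fitness = mfit[seq_len(k)])
  structure(traj, class = c("drive_trajectory", "data.frame"),
            final = list(freq = F_freq, generation = gen),
            converged = converged, stop = stop)
}
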