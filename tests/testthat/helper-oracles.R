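# Independent oracles for the deterministic engines.
#
# brute_force_next: plain-loop enumeration of all (mother genotype, father
# genotype, mother gamete, father gamete) tuples for a diploid model —
# no matrix algebra shared with the implementation.
#
# wf_next_*: one generation of an individual-based Wright-Fisher style
# simulator (finite population, multinomial sampling) whose per-individual
# logic is written from the model rules directly.

brute_force_next <- function(freq, table, transmit_f, transmit_m, wf, wm) {
  n <- table$n
  L <- length(table$loci)
  haps <- enumerate_genotypes(table$loci, ploidy = 1L)
  out <- numeric(n)
  pf <- freq * wf; pf <- pf / sum(pf)
  pm <- freq * wm; pm <- pm / sum(pm)
  for (i in seq_len(n)) {        # mother
    for (j in seq_len(n)) {      # father
      pair <- pf[i] * pm[j]
      if (pair == 0) next
      for (gi in seq_len(haps$n)) {
        p_gi <- 1
        for (l in seq_len(L))
          p_gi <- p_gi * (if (haps$counts[gi, l] == 1L) transmit_f[i, l]
                          else 1 - transmit_f[i, l])
        if (p_gi == 0) next
        for (gj in seq_len(haps$n)) {
          p_gj <- 1
          for (l in seq_len(L))
            p_gj <- p_gj * (if (haps$counts[gj, l] == 1L) transmit_m[j, l]
                            else 1 - transmit_m[j, l])
          counts <- haps$counts[gi, ] + haps$counts[gj, ]
          pos <- 0L
          for (l in seq_len(L)) pos <- pos * 3L + counts[l]
          out[pos + 1L] <- out[pos + 1L] + pair * p_gi * p_gj
        }
      }
    }
  }
  out / sum(out)
}

# Individual-based one-generation simulator for the two-drive model
# (3 loci A, B, R; male-limited homing blocked by R; fertility selection).
# Returns offspring genotype frequencies from n_ind sampled offspring.
wf_next_two_drive <- function(freq, params, n_ind) {
  table <- enumerate_genotypes(c("A", "B", "R"))
  wf <- sapply(table$labels, function(g) genotype_fitness(g, params, "female"))
  wm <- sapply(table$labels, function(g) genotype_fitness(g, params, "male"))
  mothers <- sample.int(table$n, n_ind, replace = TRUE, prob = freq * wf)
  fathers <- sample.int(table$n, n_ind, replace = TRUE, prob = freq * wm)
  gamete <- function(idx, male) {
    cA <- table$counts[idx, "A"]; cB <- table$counts[idx, "B"]
    cR <- table$counts[idx, "R"]
    pA <- cA / 2; pB <- cB / 2
    if (male) {
      free <- cR == 0L
      pA <- ifelse(cA == 1L & free, params$d, pA)
      pB <- ifelse(cB == 1L & free, params$d, pB)
    }
    cbind(stats::rbinom(length(idx), 1, pA),
          stats::rbinom(length(idx), 1, pB),
          stats::rbinom(length(idx), 1, cR / 2))
  }
  counts <- gamete(mothers, male = FALSE) + gamete(fathers, male = TRUE)
  ids <- counts[, 1] * 9L + counts[, 2] * 3L + counts[, 3] + 1L
  tabulate(ids, nbins = table$n) / n_ind
}

# Individual-based one-generation simulator for the sib-mating homing model
# (haploid sexes, loci A and Q; homing as a family-level germline conversion
# event). Families are sampled from F_freq; each produces `brood` progeny,
# thinned by viability; Q-mothers' daughters sib mate with probability m,
# each taking a distinct surviving brother; everyone else is pooled and
# paired at random. Returns next-generation family frequencies.
wf_next_sib_family <- function(F_freq, s, m, d, h, n_fam, brood = 50L) {
  hapA <- c(0L, 0L, 1L, 1L); hapQ <- c(0L, 1L, 0L, 1L)  # haps: aq aQ Aq AQ
  fams <- sample.int(16L, n_fam, replace = TRUE, prob = F_freq)
  mother <- (fams - 1L) %/% 4L + 1L
  father <- (fams - 1L) %% 4L + 1L
  nA <- hapA[mother] + hapA[father]
  nQ <- hapQ[mother] + hapQ[father]
  viab <- ifelse(nA == 2L, 1 - s, ifelse(nA == 1L, 1 - h, 1))
  conv <- stats::rbinom(n_fam, 1, ifelse(nA == 1L, 2 * d - 1, 0))
  pA_fam <- ifelse(nA == 1L, ifelse(conv == 1L, 1, 0.5), nA / 2)
  q_mother <- hapQ[mother] == 1L
  pool_f <- integer(0); pool_m <- integer(0)
  sib_next <- integer(0)
  for (k in seq_len(n_fam)) {
    n_surv <- stats::rbinom(1, brood, viab[k])
    if (n_surv == 0L) next
    hA <- stats::rbinom(n_surv, 1, pA_fam[k])
    hQ <- stats::rbinom(n_surv, 1, nQ[k] / 2)
    hap <- hA * 2L + hQ + 1L
    is_f <- stats::rbinom(n_surv, 1, 0.5) == 1L
    girls <- hap[is_f]; boys <- hap[!is_f]
    if (q_mother[k] && length(girls)) {
      sib_girl <- stats::rbinom(length(girls), 1, m) == 1L
      n_pairs <- min(sum(sib_girl), length(boys))
      if (n_pairs > 0L) {
        gsel <- which(sib_girl)[seq_len(n_pairs)]
        bsel <- sample(seq_along(boys))[seq_len(n_pairs)]
        sib_next <- c(sib_next, (girls[gsel] - 1L) * 4L + boys[bsel])
        boys <- boys[-bsel]
      }
      girls <- girls[!sib_girl]  # unpaired sib-designated daughters are lost
    }
    pool_f <- c(pool_f, girls); pool_m <- c(pool_m, boys)
  }
  n_pairs <- min(length(pool_f), length(pool_m))
  rand_next <- (sample(pool_f)[seq_len(n_pairs)] - 1L) * 4L +
    sample(pool_m)[seq_len(n_pairs)]
  tabulate(c(sib_next, rand_next), nbins = 16L) /
    (length(sib_next) + n_pairs)
}

expect_within_sampling_error <- function(observed, expected, n, factor = 5) {
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(observed - expected) <= factor * se + 1e-9),
              label = paste("max standardized deviation",
                            max(abs(observed - expected) / se)))
}
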