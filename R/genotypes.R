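#' Enumerate multilocus genotypes
#'
#' Builds the complete, stably ordered table of multilocus genotypes for a set
#' of unlinked biallelic loci. Each locus is labelled by a single letter; the
#' uppercase form denotes the derived allele (drive, resistance, sib-mating,
#' ...) and the lowercase form the wild type. Diploid loci have three
#' genotypes (e.g. `aa`, `Aa`, `AA`; unordered heterozygotes are collapsed),
#' haploid loci have two. The table therefore has `3^L` rows for `L` diploid
#' loci and `2^L` rows for `L` haploid loci.
#'
#' Ordering is lexicographic over loci with the count of the uppercase allele
#' ascending, the first locus varying slowest. The ordering is stable so that
#' exported frequency tables are reproducible bit-for-bit.
#'
#' @param loci character vector of single-letter locus labels (1 to 4 loci).
#' @param ploidy integer, 1 (haploid) or 2 (diploid); recycled over loci.
#' @return An object of class `genotype_table`: a list with elements `loci`,
#'   `ploidy`, `counts` (matrix, one row per genotype, one column per locus,
#'   entries = copies of the uppercase allele), `labels`, `index` (named
#'   integer vector mapping label to row) and `n`.
#' @examples
#' enumerate_genotypes(c("A", "B", "R"))     # 27 diploid genotypes
#' enumerate_genotypes("A")                  # aa, Aa, AA
#' enumerate_genotypes(c("A", "Q"), ploidy = 1)  # 4 haplotypes
#' @export
enumerate_genotypes <- function(loci, ploidy = 2) {
  loci <- as.character(loci)
  if (length(loci) < 1L || length(loci) > 4L)
    stop("between 1 and 4 loci are supported")
  if (anyDuplicated(loci))
    stop("duplicate locus labels: ", paste(loci[duplicated(loci)], collapse = ", "))
  if (!all(nchar(loci) == 1L))
    stop("locus labels must be single letters")
  ploidy <- rep_len(as.integer(ploidy), length(loci))
  if (!all(ploidy %in% c(1L, 2L)))
    stop("ploidy must be 1 or 2")

  L <- length(loci)
  # first locus varies slowest
  grid <- expand.grid(rev(lapply(ploidy, function(p) 0:p)),
                      KEEP.OUT.ATTRS = FALSE)
  counts <- as.matrix(grid[, rev(seq_len(L)), drop = FALSE])
  dimnames(counts) <- list(NULL, loci)
  storage.mode(counts) <- "integer"

  labels <- apply(counts, 1L, function(row) {
    paste(vapply(seq_len(L), function(l) {
      up <- toupper(loci[l]); lo <- tolower(loci[l])
      paste(c(rep(up, row[l]), rep(lo, ploidy[l] - row[l])), collapse = "")
    }, character(1)), collapse = "")
  })

  structure(
    list(loci = loci, ploidy = ploidy, counts = counts, labels = labels,
         index = stats::setNames(seq_along(labels), labels),
         n = length(labels)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  kind <- if (all(x$ploidy == 1L)) "haplotypes" else "genotypes"
  cat(sprintf("genotype_table: %d %s at %d unlinked loci (%s)\n",
              x$n, kind, length(x$loci), paste(x$loci, collapse = ", ")))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Per-locus allele frequencies of a genotype-frequency vector
#'
#' @param freq numeric vector of genotype frequencies, in the row order of
#'   `table`.
#' @param table a [genotype_table][enumerate_genotypes].
#' @return named numeric vector, the frequency of the uppercase allele at
#'   each locus.
#' @export
allele_frequencies <- function(freq, table) {
  stopifnot(length(freq) == table$n)
  drop(crossprod(table$counts, freq)) / (table$ploidy * sum(freq))
}

# row index of the genotype with the given per-locus uppercase counts
genotype_row <- function(table, counts) {
  # mixed-radix, first locus most significant
  pos <- 0L
  for (l in seq_along(table$loci))
    pos <- pos * (table$ploidy[l] + 1L) + counts[l]
  unname(pos) + 1L
}

# Hardy-Weinberg joint genotype frequencies for independent loci, given the
# per-locus uppercase allele frequencies (named or in table locus order).
hardy_weinberg_state <- function(table, p) {
  if (!is.null(names(p))) p <- p[table$loci]
  stopifnot(length(p) == length(table$loci), all(p >= 0), all(p <= 1))
  freq <- rep(1, table$n)
  for (l in seq_along(table$loci)) {
    c_l <- table$counts[, l]
    freq <- freq * stats::dbinom(c_l, table$ploidy[l], p[l])
  }
  freq
}
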