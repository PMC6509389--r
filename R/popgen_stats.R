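#' Unbiased expected heterozygosity
#'
#' Nei's sample-size-corrected gene diversity for one locus,
#' \eqn{uHe = \frac{2n}{2n-1}(1 - \sum_a p_a^2)}, with `n` the number of
#' diploid individuals scored.
#'
#' @param freqs numeric allele frequency vector (sums to 1).
#' @param n diploid sample size (individuals scored at the locus).
#' @return a value in `[0, 1)`; 0 for a monomorphic locus.
#' @export
unbiased_He <- function(freqs, n) {
  if (length(freqs) == 0 || n < 1) stop("need frequencies and n >= 1")
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' \eqn{AR(g) = \sum_a [1 - C(N - N_a, g) / C(N, g)]} where `N_a` are
#' per-allele gene-copy counts and `N` their total.
#'
#' @param counts integer vector of per-allele gene-copy counts (all > 0).
#' @param g rarefaction gene-copy count, `1 <= g <= sum(counts)`.
#' @return expected allele number in `[1, length(counts)]`; equals
#'   `length(counts)` at `g = sum(counts)`.
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must be between 1 and the total gene count")
  # lchoose handles C(N - Na, g) = 0 when g > N - Na
  p_absent <- exp(lchoose(N - counts, g) - lchoose(N, g))
  sum(1 - p_absent)
}

#' Private alleles per population
#'
#' An allele is private to a population if it is observed there and in no
#' other population. Reported per population as the count of private alleles
#' across loci divided by the number of loci.
#'
#' @param x a `genotype_table`.
#' @param populations list of character vectors of site labels, one per
#'   population (or `NULL`: every site is its own population).
#' @return named numeric vector of mean private alleles per locus.
#' @export
private_alleles <- function(x, populations = NULL) {
  if (is.null(populations)) {
    populations <- as.list(unique(x$site))
    names(populations) <- unique(x$site)
  }
  if (length(populations) < 2) stop("need at least two populations")
  if (is.null(names(populations))) {
    names(populations) <- vapply(populations, paste, "", collapse = "+")
  }
  L <- n_loci(x)
  counts <- lapply(populations, function(g) allele_counts(x, g))
  present <- lapply(counts, function(cl) lapply(cl, names))
  out <- vapply(seq_along(populations), function(i) {
    npriv <- 0L
    for (j in seq_len(L)) {
      mine <- present[[i]][[j]]
      others <- unique(unlist(lapply(
        seq_along(populations)[-i], function(k) present[[k]][[j]]
      )))
      npriv <- npriv + sum(!mine %in% others)
    }
    npriv / L
  }, numeric(1))
  stats::setNames(out, names(populations))
}

# log conditional probability of a genotype array given allele counts
# (Levene / Guo-Thompson): depends on data only through het count and
# genotype multiplicities; the allele-count terms are permutation-invariant
# and dropped.
log_genotype_array_stat <- function(a1, a2) {
  het <- sum(a1 != a2)
  g <- paste(pmin(a1, a2), pmax(a1, a2))
  het * log(2) - sum(lgamma(table(g) + 1))
}

#' Monte Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Tests one locus in one population by permuting the observed gene copies
#' into random diploid genotypes and comparing the conditional probability of
#' the genotype array given the allele counts (Guo-Thompson style statistic).
#' Arrays at least as improbable as the observed one count as extreme. The
#' p-value uses the add-one estimator
#' `(1 + #extreme) / (n_perm + 1)`.
#'
#' @param a1,a2 integer allele vectors for the scored individuals (no `NA`).
#' @param n_perm number of Monte Carlo permutations.
#' @param seed optional integer seed for reproducibility.
#' @return a list with `p_value` and `testable`; a monomorphic locus is not
#'   testable (`p_value` is `NA`).
#' @export
hwe_exact_test <- function(a1, a2, n_perm = 10000, seed = NULL) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  genes <- c(a1, a2)
  if (length(unique(genes)) < 2) {
    return(list(p_value = NA_real_, testable = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- log_genotype_array_stat(a1, a2)
  n <- length(a1)
  extreme <- 0L
  for (r in seq_len(n_perm)) {
    perm <- sample(genes)
    stat <- log_genotype_array_stat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (stat <= obs + 1e-12) extreme <- extreme + 1L
  }
  list(p_value = (1 + extreme) / (n_perm + 1), testable = TRUE)
}

two_locus_g_stat <- function(g1, g2) {
  tab <- table(g1, g2)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Association between single-locus genotypes at two loci within one
#' population, measured by the G statistic (log likelihood ratio) on the
#' genotype-by-genotype contingency table. The null distribution is built by
#' permuting one locus's genotypes across individuals, which breaks the
#' between-locus association while preserving both single-locus genotype
#' arrays. Same add-one p-value estimator as [hwe_exact_test()].
#'
#' @param l1_a1,l1_a2 allele vectors at locus 1.
#' @param l2_a1,l2_a2 allele vectors at locus 2 (same individuals).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return a list with `p_value` and `testable`; either locus monomorphic
#'   makes the pair untestable.
#' @export
ld_permutation_test <- function(l1_a1, l1_a2, l2_a1, l2_a2,
                                n_perm = 10000, seed = NULL) {
  keep <- !is.na(l1_a1) & !is.na(l2_a1)
  l1_a1 <- l1_a1[keep]; l1_a2 <- l1_a2[keep]
  l2_a1 <- l2_a1[keep]; l2_a2 <- l2_a2[keep]
  if (length(unique(c(l1_a1, l1_a2))) < 2 ||
      length(unique(c(l2_a1, l2_a2))) < 2) {
    return(list(p_value = NA_real_, testable = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  g1 <- paste(pmin(l1_a1, l1_a2), pmax(l1_a1, l1_a2))
  g2 <- paste(pmin(l2_a1, l2_a2), pmax(l2_a1, l2_a2))
  obs <- two_locus_g_stat(g1, g2)
  extreme <- 0L
  for (r in seq_len(n_perm)) {
    stat <- two_locus_g_stat(g1, sample(g2))
    if (stat >= obs - 1e-12) extreme <- extreme + 1L
  }
  list(p_value = (1 + extreme) / (n_perm + 1), testable = TRUE)
}

#' Bonferroni significance flags
#'
#' Flags `p < alpha / m` where `m` defaults to the number of performed
#' tests, i.e. the length of `pvalues` after dropping `NA` (untestable)
#' entries.
#'
#' @param pvalues numeric vector (may contain `NA` for untestable cases).
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests for the correction; defaults to the number of
#'   non-`NA` p-values.
#' @return logical vector (`NA` where the test was not performed).
#' @export
bonferroni <- function(pvalues, alpha = 0.05, m = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(pvalues)) return(logical(0))
  if (is.null(m)) m <- sum(!is.na(pvalues))
  ifelse(is.na(pvalues), NA, pvalues < alpha / m)
}

#' Population-genetic summary table
#'
#' Per-population summaries for the population-level sites of a genotype
#' table: sample size `N`, total alleles `A` across loci, mean unbiased
#' expected heterozygosity `uHe`, monomorphic locus count `ML`, rarefied
#' allelic richness `AR`, mean private alleles `PA`, and the number of loci
#' (`HWE_fail`) and locus pairs (`LD_fail`) significant after Bonferroni
#' correction across all performed tests.
#'
#' @param x a `genotype_table`.
#' @param min_pop_size threshold for population-level sites.
#' @param g rarefaction gene-copy count; default `2 * min_pop_size` (the
#'   smallest possible population-level sample).
#' @param n_perm Monte Carlo permutations for the HWE and LD tests.
#' @param alpha family-wise significance level.
#' @param seed integer seed for the permutation tests.
#' @return a data.frame with one row per population-level site, plus
#'   attributes `n_hwe_tests` and `n_ld_tests` (performed test counts used as
#'   the Bonferroni denominators).
#' @export
pop_summary <- function(x, min_pop_size = 11, g = 2 * min_pop_size,
                        n_perm = 1000, alpha = 0.05, seed = 1L) {
  cls <- classify_sites(x, min_pop_size)
  pops <- cls$population
  if (!length(pops)) stop("no population-level sites at this threshold")
  L <- n_loci(x)
  pa <- if (length(pops) >= 2) {
    private_alleles(x, stats::setNames(as.list(pops), pops))
  } else {
    stats::setNames(rep(NA_real_, length(pops)), pops)
  }

  hwe_p <- matrix(NA_real_, length(pops), L, dimnames = list(pops, x$loci))
  ld_p <- list()
  rows <- list()
  for (pi in seq_along(pops)) {
    p <- pops[pi]
    sel <- which(x$site == p)
    counts <- allele_counts(x, p)
    freqs <- allele_frequencies(x, p)
    A <- sum(vapply(counts, length, integer(1)))
    ml <- sum(vapply(counts, function(cc) length(cc) <= 1, logical(1)))
    uhe <- mean(vapply(seq_len(L), function(j) {
      nj <- freqs[[j]]$n_genes / 2
      if (nj < 1) return(NA_real_)
      unbiased_He(freqs[[j]]$freq, nj)
    }, numeric(1)), na.rm = TRUE)
    ar <- mean(vapply(counts, function(cc) {
      N <- sum(cc)
      if (N < g) return(NA_real_)
      allelic_richness(cc, g)
    }, numeric(1)), na.rm = TRUE)
    for (j in seq_len(L)) {
      res <- hwe_exact_test(x$a1[sel, j], x$a2[sel, j], n_perm,
                            seed = seed + 1000L * pi + j)
      hwe_p[pi, j] <- res$p_value
    }
    for (j1 in seq_len(L - 1)) {
      for (j2 in seq(j1 + 1, L)) {
        res <- ld_permutation_test(
          x$a1[sel, j1], x$a2[sel, j1], x$a1[sel, j2], x$a2[sel, j2],
          n_perm, seed = seed + 100000L * pi + 100L * j1 + j2
        )
        ld_p[[length(ld_p) + 1L]] <- list(pop = p, p_value = res$p_value)
      }
    }
    rows[[pi]] <- data.frame(
      site = p, N = length(sel), A = A, uHe = uhe, ML = ml,
      AR = ar, PA = unname(pa[p])
    )
  }
  out <- do.call(rbind, rows)

  hwe_vec <- as.vector(hwe_p)
  hwe_flags <- matrix(bonferroni(hwe_vec, alpha), nrow(hwe_p))
  out$HWE_fail <- apply(hwe_flags, 1, function(fl) sum(fl, na.rm = TRUE))
  ld_pop <- vapply(ld_p, function(e) e$pop, "")
  ld_pv <- vapply(ld_p, function(e) e$p_value, numeric(1))
  ld_flags <- bonferroni(ld_pv, alpha)
  out$LD_fail <- vapply(pops, function(p) {
    sum(ld_flags[ld_pop == p], na.rm = TRUE)
  }, numeric(1))
  attr(out, "n_hwe_tests") <- sum(!is.na(hwe_vec))
  attr(out, "n_ld_tests") <- sum(!is.na(ld_pv))
  rownames(out) <- NULL
  out
}
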