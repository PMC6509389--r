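#' Labelled symmetric distance matrices
#'
#' Lightweight container used for all pairwise matrices in the package: a
#' base matrix with row/column labels plus `metric` and `level` attributes.
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param labels character labels (individuals or sites).
#' @param metric metric tag, e.g. `"dps_distance"`, `"bray_curtis"`,
#'   `"nei_da"`, `"fst"`, `"effective_resistance"`.
#' @param level `"individual"` or `"population"`.
#' @return the matrix with class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        metric = "unknown",
                        level = c("population", "individual")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  if (max(abs(values - t(values))) > 1e-8) stop("matrix must be symmetric")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"),
            metric = metric, level = level)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s, %s level, %d labels\n",
              attr(x, "metric"), attr(x, "level"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Lower-triangle vector of a distance matrix
#'
#' @param x a square matrix.
#' @return numeric vector of the strictly-lower-triangle entries, ordered
#'   column-major as in [lower.tri()].
#' @export
lower_triangle <- function(x) {
  x <- as.matrix(x)
  x[lower.tri(x)]
}

# per-individual allele count list: one (N x k_l) 0/1/2 matrix per locus,
# rows NA when the call is missing
allele_count_matrices <- function(x) {
  lapply(seq_along(x$loci), function(j) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    C <- matrix(0, length(x$id), max(length(alleles), 1L),
                dimnames = list(x$id, as.character(alleles)))
    called <- which(!is.na(a1))
    if (length(alleles) && length(called)) {
      C[cbind(called, match(a1[called], alleles))] <- 1
      idx2 <- cbind(called, match(a2[called], alleles))
      C[idx2] <- C[idx2] + 1
    }
    C[is.na(a1), ] <- NA
    C
  })
}

#' Allele-sharing distance between two individuals
#'
#' One minus the proportion of shared alleles (Dps):
#' `1 - sum_l sum_a min(c1, c2) / (2 * L_obs)` over the loci where both
#' individuals are called, with `c` the per-individual allele counts in
#' \{0, 1, 2\}.
#'
#' @param ind1,ind2 lists with elements `a1` and `a2`: integer allele vectors
#'   over loci (NA = missing call).
#' @return distance in `[0, 1]`; 0 for identical genotypes.
#' @export
dps_pair <- function(ind1, ind2) {
  shared_and_loci(ind1, ind2, denom = "loci")
}

#' Bray-Curtis dissimilarity between two individuals
#'
#' `1 - 2 * sum(min(c1, c2)) / (sum(c1) + sum(c2))` on the concatenated
#' per-locus allele-count vectors over co-called loci. For complete diploid
#' data this equals the allele-sharing distance [dps_pair()] exactly, since
#' both count totals are `2 * L`.
#'
#' @inheritParams dps_pair
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis_pair <- function(ind1, ind2) {
  shared_and_loci(ind1, ind2, denom = "counts")
}

shared_and_loci <- function(ind1, ind2, denom) {
  ok <- !is.na(ind1$a1) & !is.na(ind2$a1)
  if (!any(ok)) stop("no locus called in both individuals")
  shared <- 0
  for (j in which(ok)) {
    g1 <- c(ind1$a1[j], ind1$a2[j])
    g2 <- c(ind2$a1[j], ind2$a2[j])
    alleles <- union(g1, g2)
    c1 <- vapply(alleles, function(a) sum(g1 == a), numeric(1))
    c2 <- vapply(alleles, function(a) sum(g2 == a), numeric(1))
    shared <- shared + sum(pmin(c1, c2))
  }
  if (denom == "loci") 1 - shared / (2 * sum(ok))
  else 1 - 2 * shared / (4 * sum(ok))
}

#' Pairwise individual distance matrix
#'
#' Allele-sharing (Dps) or Bray-Curtis distances between all pairs of
#' individuals. Computed per locus from 0/1/2 allele-count matrices using the
#' identity `sum(min) = (sum(c1) + sum(c2) - manhattan) / 2`, so the cost is
#' one Manhattan [dist()] per locus. Pairs never called at a common locus get
#' `NA`.
#'
#' @param x a `genotype_table`.
#' @param metric `"dps_distance"` or `"bray_curtis"`.
#' @return a [dist_matrix()] at individual level.
#' @export
individual_distances <- function(x, metric = c("dps_distance",
                                               "bray_curtis")) {
  metric <- match.arg(metric)
  N <- n_individuals(x)
  Cs <- allele_count_matrices(x)
  shared <- matrix(0, N, N)
  nobs <- matrix(0L, N, N)
  for (C in Cs) {
    called <- !is.na(C[, 1])
    if (sum(called) < 2) next
    sub <- C[called, , drop = FALSE]
    man <- as.matrix(stats::dist(sub, method = "manhattan"))
    sh <- (4 - man) / 2  # each row sums to 2 gene copies
    idx <- which(called)
    shared[idx, idx] <- shared[idx, idx] + sh
    nobs[idx, idx] <- nobs[idx, idx] + 1L
  }
  vals <- matrix(NA_real_, N, N)
  ok <- nobs > 0
  vals[ok] <- 1 - shared[ok] / (2 * nobs[ok])
  diag(vals) <- 0
  dist_matrix(vals, x$id, metric = metric, level = "individual")
}

#' Average an individual matrix to population level
#'
#' Entry (i, j) of the result is the mean of the individual distances over
#' all cross-site pairs (one individual from site i, one from site j); the
#' diagonal is 0 by convention. Single-individual sites are allowed.
#'
#' @param ind_matrix individual-level [dist_matrix()].
#' @param site_of named character vector mapping individual id to site.
#' @return a population-level [dist_matrix()] with the same metric tag.
#' @export
average_to_population <- function(ind_matrix, site_of) {
  ids <- rownames(ind_matrix)
  if (!all(ids %in% names(site_of))) {
    stop("every individual must be mapped to a site")
  }
  sites <- unique(site_of[ids])
  if (length(sites) < 2) stop("need at least two sites")
  P <- length(sites)
  out <- matrix(0, P, P, dimnames = list(sites, sites))
  members <- lapply(sites, function(s) which(site_of[ids] == s))
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      block <- ind_matrix[members[[i]], members[[j]], drop = FALSE]
      out[i, j] <- out[j, i] <- mean(block)
    }
  }
  dist_matrix(out, sites, metric = attr(ind_matrix, "metric"),
              level = "population")
}

#' Population-level allele-sharing distances
#'
#' Convenience wrapper: individual Dps distances averaged over all cross-site
#' individual pairs.
#'
#' @param x a `genotype_table`.
#' @return a population-level [dist_matrix()].
#' @export
population_dps <- function(x) {
  ind <- individual_distances(x, "dps_distance")
  average_to_population(ind, stats::setNames(x$site, x$id))
}

#' Nei's Da distance between two frequency profiles
#'
#' `Da = 1 - (1/L) * sum_l sum_a sqrt(x_a * y_a)`.
#'
#' @param freqA,freqB lists of named per-locus allele frequency vectors with
#'   matching locus sets (as from [allele_frequencies()], `$freq` elements).
#' @return distance in `[0, 1]`.
#' @export
nei_da <- function(freqA, freqB) {
  if (length(freqA) != length(freqB)) stop("unmatched locus sets")
  L <- length(freqA)
  s <- 0
  for (j in seq_len(L)) {
    fa <- freqA[[j]]; fb <- freqB[[j]]
    alleles <- union(names(fa), names(fb))
    xa <- stats::setNames(rep(0, length(alleles)), alleles)
    ya <- xa
    xa[names(fa)] <- fa; ya[names(fb)] <- fb
    s <- s + sum(sqrt(xa * ya))
  }
  1 - s / L
}

#' Weir-Cockerham theta between two populations
#'
#' Weir & Cockerham's (1984) estimator of Fst from the a, b, c variance
#' components, summed over alleles and loci: `theta = sum(a) / sum(a+b+c)`.
#' Per-locus sample sizes reflect missing data. Slightly negative estimates
#' are retained.
#'
#' @param x a `genotype_table`.
#' @param popA,popB character vectors of site labels defining the two
#'   population samples.
#' @return theta estimate (`NA` with a warning if every shared locus is
#'   monomorphic across the two samples).
#' @export
fst_pair <- function(x, popA, popB) {
  comp <- wc_components(x, popA, popB)
  if (comp$denom <= 0) {
    warning("all shared loci monomorphic; theta undefined")
    return(NA_real_)
  }
  comp$num / comp$denom
}

wc_components <- function(x, popA, popB) {
  selA <- which(x$site %in% popA)
  selB <- which(x$site %in% popB)
  num <- 0; denom <- 0
  r <- 2
  for (j in seq_len(n_loci(x))) {
    gA1 <- x$a1[selA, j]; gA2 <- x$a2[selA, j]
    gB1 <- x$a1[selB, j]; gB2 <- x$a2[selB, j]
    okA <- !is.na(gA1); okB <- !is.na(gB1)
    n1 <- sum(okA); n2 <- sum(okB)
    if (n1 < 1 || n2 < 1) next
    alleles <- unique(c(gA1[okA], gA2[okA], gB1[okB], gB2[okB]))
    if (length(alleles) < 2) next
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (a in alleles) {
      p1 <- (sum(gA1[okA] == a) + sum(gA2[okA] == a)) / (2 * n1)
      p2 <- (sum(gB1[okB] == a) + sum(gB2[okB] == a)) / (2 * n2)
      h1 <- sum((gA1[okA] == a) != (gA2[okA] == a)) / n1
      h2 <- sum((gB1[okB] == a) != (gB2[okB] == a)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      if (nbar <= 1) next
      av <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      bv <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cv <- hbar / 2
      num <- num + av
      denom <- denom + av + bv + cv
    }
  }
  list(num = num, denom = denom)
}

#' Population-level Nei's Da or Fst matrix
#'
#' @param x a `genotype_table`.
#' @param metric `"nei_da"` or `"fst"`.
#' @param sites site labels to include (default all).
#' @return a population-level [dist_matrix()].
#' @export
population_distances <- function(x, metric = c("nei_da", "fst"),
                                 sites = unique(x$site)) {
  metric <- match.arg(metric)
  P <- length(sites)
  if (P < 2) stop("need at least two sites")
  freqs <- lapply(sites, function(s) {
    lapply(allele_frequencies(x, s), `[[`, "freq")
  })
  out <- matrix(0, P, P, dimnames = list(sites, sites))
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      v <- if (metric == "nei_da") {
        nei_da(freqs[[i]], freqs[[j]])
      } else {
        fst_pair(x, sites[i], sites[j])
      }
      out[i, j] <- out[j, i] <- v
    }
  }
  dist_matrix(out, sites, metric = metric, level = "population")
}

#' Correlation between two distance matrices
#'
#' Pearson correlation (or its square) over the strictly-lower-triangle
#' entries of two matrices with identical labels.
#'
#' @param dm1,dm2 [dist_matrix()] objects with the same labels and level.
#' @param statistic `"r"` or `"r2"`.
#' @return scalar correlation.
#' @export
index_correlation <- function(dm1, dm2, statistic = c("r", "r2")) {
  statistic <- match.arg(statistic)
  if (!identical(rownames(dm1), rownames(dm2))) {
    stop("matrices must share labels")
  }
  if (nrow(dm1) < 3) stop("need at least 3 labels")
  v1 <- lower_triangle(dm1); v2 <- lower_triangle(dm2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("correlation undefined for a constant matrix")
  }
  r <- stats::cor(v1, v2)
  if (statistic == "r") r else r^2
}

#' Read a square labelled distance matrix from CSV
#'
#' Inverse of [write_dist_matrix()] with `format = "square"`.
#'
#' @param path CSV path (first column `label`, then one column per label).
#' @param metric,level tags for the returned object.
#' @return a [dist_matrix()].
#' @export
read_dist_matrix <- function(path, metric = "unknown",
                             level = "population") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dist_matrix(m, labels, metric = metric, level = level)
}

#' Write a distance matrix as CSV
#'
#' @param x a [dist_matrix()].
#' @param path output path.
#' @param format `"square"` (labelled square matrix) or `"long"`
#'   (`site_i, site_j, value`, lower triangle only).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(x, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(lower.tri(x), arr.ind = TRUE)
    df <- data.frame(
      site_i = rownames(x)[idx[, "row"]],
      site_j = colnames(x)[idx[, "col"]],
      value = x[idx]
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
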