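# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (dense algebra, literal formula
# transcription) and never call the package code paths they check.

# small two-site diploid table: 4 individuals, 2 loci
toy_table <- function() {
  genotype_table(
    id = c("a1", "a2", "b1", "b2"),
    site = c("A", "A", "B", "B"),
    loci = c("L1", "L2"),
    a1 = matrix(c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L), 4, 2),
    a2 = matrix(c(1L, 2L, 2L, 2L, 3L, 4L, 4L, 5L), 4, 2)
  )
}

# random complete-data genotype table
random_table <- function(n_ind = 20, n_loci = 5, n_sites = 4,
                         n_alleles = 6, seed = 1) {
  set.seed(seed)
  genotype_table(
    id = sprintf("i%03d", seq_len(n_ind)),
    site = sample(sprintf("s%d", seq_len(n_sites)), n_ind, replace = TRUE),
    loci = sprintf("L%d", seq_len(n_loci)),
    a1 = matrix(sample.int(n_alleles, n_ind * n_loci, TRUE), n_ind, n_loci),
    a2 = matrix(sample.int(n_alleles, n_ind * n_loci, TRUE), n_ind, n_loci)
  )
}

# literal per-pair allele-sharing distance (slow double loop)
dps_oracle <- function(tab, i, j) {
  shared <- 0; nloc <- 0
  for (l in seq_along(tab$loci)) {
    g1 <- c(tab$a1[i, l], tab$a2[i, l])
    g2 <- c(tab$a1[j, l], tab$a2[j, l])
    if (any(is.na(g1)) || any(is.na(g2))) next
    nloc <- nloc + 1
    for (a in unique(c(g1, g2))) {
      shared <- shared + min(sum(g1 == a), sum(g2 == a))
    }
  }
  1 - shared / (2 * nloc)
}

# dense Moore-Penrose effective-resistance oracle
resistance_oracle <- function(laplacian, idx_i, idx_j) {
  Lp <- MASS::ginv(as.matrix(laplacian))
  e <- rep(0, nrow(Lp))
  e[idx_i] <- 1; e[idx_j] <- -1
  drop(t(e) %*% Lp %*% e)
}

# dense multivariate-normal MLPE log-likelihood at given phi (explicit V,
# direct inverse and determinant); profile sigma_e^2 in closed form
mlpe_dense_loglik <- function(y, X, Z, phi, method) {
  n <- length(y); p <- ncol(X)
  Vstar <- diag(n) + phi * tcrossprod(Z)
  Vi <- solve(Vstar)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  ldet <- determinant(Vstar, logarithm = TRUE)$modulus
  if (method == "ML") {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + ldet + n)
  } else {
    s2 <- rss / (n - p)
    ldx <- determinant(XtVi %*% X, logarithm = TRUE)$modulus
    # |X' V^-1 X| with V = s2 Vstar
    -0.5 * ((n - p) * log(2 * pi * s2) + ldet + ldx + (n - p))
  }
}

# grid-search maximization of the dense likelihood over phi: coarse
# log-scale pass (plus the phi = 0 boundary), then a fine pass around the
# coarse argmax
mlpe_grid_oracle <- function(y, X, Z, method) {
  eval_grid <- function(grid) {
    vapply(grid, function(phi) {
      mlpe_dense_loglik(y, X, Z, phi, method)
    }, numeric(1))
  }
  coarse <- c(0, 10^seq(-4, 4, by = 0.01))
  ll <- eval_grid(coarse)
  best <- coarse[which.max(ll)]
  fine <- if (best == 0) {
    seq(0, 2e-4, by = 1e-7)
  } else {
    seq(best * 0.95, best * 1.05, length.out = 8001)
  }
  llf <- eval_grid(fine)
  list(loglik = max(llf), phi = fine[which.max(llf)])
}

# naive Weir-Cockerham theta for two populations, literal transcription
wc_theta_oracle <- function(tab, popA, popB) {
  selA <- which(tab$site %in% popA)
  selB <- which(tab$site %in% popB)
  num <- 0; den <- 0
  for (l in seq_along(tab$loci)) {
    gA <- cbind(tab$a1[selA, l], tab$a2[selA, l])
    gB <- cbind(tab$a1[selB, l], tab$a2[selB, l])
    gA <- gA[stats::complete.cases(gA), , drop = FALSE]
    gB <- gB[stats::complete.cases(gB), , drop = FALSE]
    n1 <- nrow(gA); n2 <- nrow(gB)
    if (n1 < 1 || n2 < 1) next
    alleles <- unique(c(gA, gB))
    if (length(alleles) < 2) next
    nbar <- (n1 + n2) / 2
    nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar))
    for (al in alleles) {
      p1 <- mean(gA == al); p2 <- mean(gB == al)
      h1 <- mean((gA[, 1] == al) != (gA[, 2] == al))
      h2 <- mean((gB[, 1] == al) != (gB[, 2] == al))
      pb <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pb)^2 + n2 * (p2 - pb)^2) / nbar
      hb <- (n1 * h1 + n2 * h2) / (n1 + n2)
      a <- (nbar / nc) *
        (s2 - (pb * (1 - pb) - s2 / 2 - hb / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pb * (1 - pb) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hb)
      cc <- hb / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# symmetric matrix with zero diagonal from a lower-triangle vector
sym_from_lower <- function(v, P, labels = sprintf("s%d", seq_len(P))) {
  m <- matrix(0, P, P)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}

# small cached synthetic study shared by the slower tests
cached_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        nrow = 50, ncol = 50, n_sites = 12, min_sep = 5,
        sample_sizes = c(rep(12L, 8), 2L, 3L, 1L, 4L),
        generations = 60
      )
      cache <<- simulate_ibr_study(cfg, seed = 42)
    }
    cache
  }
})
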