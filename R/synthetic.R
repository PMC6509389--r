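#' Configuration for the synthetic isolation-by-resistance study
#'
#' Bundles every knob of the generator: the landscape grid, the cover-class
#' mix, the site layout, the demography of the forward simulation, and the
#' marker panel. Defaults emulate a pond-breeding amphibian microsatellite
#' survey: 40 sites of uneven sample size (1-25 individuals, 334 total, 18
#' sites at >= 11), 8 loci with up to a dozen founding alleles each, and
#' genetic divergence driven by effective resistance through one causal
#' land-cover class.
#'
#' @param nrow,ncol raster dimensions in cells.
#' @param cellsize cell edge length in metres.
#' @param cover_fractions named numeric vector of land-cover class area
#'   fractions (must sum to 1; realized exactly via quantile thresholds).
#' @param autocorr_range spatial autocorrelation length of the underlying
#'   Gaussian fields, in cells.
#' @param n_sites number of sampling sites.
#' @param min_sep minimum pairwise site separation in cells.
#' @param causal_class cover class through which resistance acts on gene
#'   flow.
#' @param causal_resistance resistance of causal-class cells in the
#'   generating surface (non-causal cells have resistance 1). Large values
#'   give a strong isolation-by-resistance signal.
#' @param Ne diploid effective size per deme.
#' @param m0 total emigration fraction per deme per generation (< 0.5 so
#'   demes retain a majority of residents).
#' @param rho resistance decay scale of migration,
#'   `m_ij proportional to exp(-R_ij / rho)`; `NULL` = median pairwise
#'   effective resistance.
#' @param generations forward Wright-Fisher generations.
#' @param n_loci,n_alleles loci and founding alleles per locus.
#' @param sample_sizes integer vector of per-site sample sizes (recycled or
#'   truncated to `n_sites`).
#' @param founder_freqs optional list of named per-locus founding allele
#'   frequency vectors (names = allele codes), overriding the equifrequent
#'   default; e.g. [microsat_panel_freqs()].
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(nrow = 100, ncol = 100, cellsize = 400,
                             cover_fractions = c(
                               forest_ld = 0.20, forest_hd = 0.15,
                               shrub = 0.15, grass = 0.15,
                               ag = 0.20, dev = 0.15
                             ),
                             autocorr_range = 12,
                             n_sites = 40, min_sep = 8,
                             causal_class = "forest_ld",
                             causal_resistance = 50,
                             Ne = 50, m0 = 0.3, rho = NULL,
                             generations = 80,
                             n_loci = 8, n_alleles = 12,
                             sample_sizes = default_sample_sizes(),
                             founder_freqs = NULL) {
  stopifnot(sum(cover_fractions) <= 1 + 1e-9, Ne >= 2,
            m0 > 0, m0 < 1, generations >= 1, all(sample_sizes >= 1))
  if (!causal_class %in% names(cover_fractions)) {
    stop("causal_class must be one of the cover classes")
  }
  sample_sizes <- rep_len(sample_sizes, n_sites)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default uneven per-site sample sizes
#'
#' 40 sites totalling 334 individuals: 18 population-level sites of 11-25
#' individuals and 22 sparse sites of 1-10, the kind of skew that field
#' surveys of patchily abundant amphibians produce.
#'
#' @return integer vector of length 40.
#' @export
default_sample_sizes <- function() {
  c(15L, 21L, 11L, 11L, 15L, 16L, 14L, 11L, 11L, 25L, 18L, 14L, 16L, 20L,
    12L, 17L, 11L, 18L,
    rep(1L, 8), rep(2L, 6), rep(3L, 3), rep(4L, 2), 5L, 6L, 10L)
}

# smoothed Gaussian random field on an nr x nc grid (separable kernel,
# reflecting edges), standardized to mean 0 sd 1
smooth_field <- function(nr, nc, range_cells) {
  half <- max(1L, ceiling(2 * range_cells))
  kern <- exp(-0.5 * ((-half:half) / range_cells)^2)
  kern <- kern / sum(kern)
  z <- matrix(stats::rnorm((nr + 2 * half) * (nc + 2 * half)),
              nr + 2 * half, nc + 2 * half)
  z <- apply(z, 2, function(col) stats::filter(col, kern, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, kern, sides = 2)))
  z <- z[half + seq_len(nr), half + seq_len(nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic classed landscape
#'
#' Cover classes are realized by slicing a smoothed Gaussian random field at
#' its empirical quantiles, so realized class fractions match the targets
#' exactly up to cell granularity. Two further independent fields give
#' continuous, strictly positive slope-like and solar-like surfaces.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `cover` (classed [landscape_raster()], integer codes in
#'   the order of `cover_fractions`), `class_codes` (named code vector),
#'   `slope`, `solar` (continuous rasters).
#' @export
generate_landscape <- function(config, seed = 1L) {
  set.seed(seed)
  nr <- config$nrow; nc <- config$ncol
  fr <- config$cover_fractions
  if (any(fr < 0) || sum(fr) > 1 + 1e-9) stop("infeasible class fractions")
  f_cover <- smooth_field(nr, nc, config$autocorr_range)
  cuts <- stats::quantile(f_cover, probs = cumsum(fr) / sum(fr),
                          names = FALSE)
  cuts[length(cuts)] <- Inf
  cls <- matrix(
    findInterval(f_cover, c(-Inf, cuts[-length(cuts)])),
    nr, nc
  )
  codes <- stats::setNames(seq_along(fr), names(fr))
  f_slope <- smooth_field(nr, nc, config$autocorr_range)
  f_solar <- smooth_field(nr, nc, config$autocorr_range)
  mk <- function(m) landscape_raster(m, cellsize = config$cellsize)
  list(
    cover = mk(cls),
    class_codes = codes,
    # slope in degrees-like units, strictly positive
    slope = mk(1 + 14 * stats::pnorm(f_slope)),
    solar = mk(100 + 100 * stats::pnorm(f_solar))
  )
}

#' Place sampling sites on a raster
#'
#' Uniform random cells subject to a minimum pairwise separation, by
#' rejection with bounded retries.
#'
#' @param raster a [landscape_raster()] (shape and mask).
#' @param n_sites number of sites.
#' @param min_sep minimum pairwise Euclidean cell distance.
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return data.frame with `site`, `row`, `col`.
#' @export
place_sites <- function(raster, n_sites, min_sep, seed = 1L,
                        max_tries = 20000) {
  set.seed(seed)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  rows <- integer(0); cols <- integer(0)
  tries <- 0L
  while (length(rows) < n_sites && tries < max_tries) {
    tries <- tries + 1L
    r <- sample.int(nr, 1); c <- sample.int(nc, 1)
    if (is.na(raster$values[r, c])) next
    if (length(rows)) {
      d2 <- (rows - r)^2 + (cols - c)^2
      if (min(d2) < min_sep^2) next
    }
    rows <- c(rows, r); cols <- c(cols, c)
  }
  if (length(rows) < n_sites) {
    stop(sprintf(
      "placed only %d of %d sites at min_sep %g after %d tries",
      length(rows), n_sites, min_sep, max_tries
    ))
  }
  data.frame(site = sprintf("s%02d", seq_len(n_sites)),
             row = rows, col = cols)
}

#' Migration matrix from a pairwise resistance matrix
#'
#' Pairwise migration decays exponentially in effective resistance above its
#' minimum, `m_ij = m0 * exp(-(R_ij - min R) / rho)`, so well-connected
#' pairs exchange close to `m0` while isolated demes receive little — the
#' property that makes divergence track resistance. If any deme's total
#' immigration would exceed 0.5, all off-diagonal entries are scaled down so
#' the largest row sum is 0.5, keeping every deme majority-resident. The
#' diagonal is the self-retention `1 - sum_j m_ij`.
#'
#' @param R symmetric pairwise resistance matrix.
#' @param m0 per-pair migration at the minimum observed resistance.
#' @param rho resistance decay scale; `NULL` defaults to half the spread
#'   between the median and minimum off-diagonal resistance.
#' @return row-stochastic migration matrix with diagonal >= 0.5.
#' @export
migration_from_resistance <- function(R, m0, rho = NULL) {
  R <- as.matrix(R)
  off <- R[lower.tri(R)]
  if (is.null(rho)) rho <- max((stats::median(off) - min(off)) / 2, 1e-8)
  w <- exp(-(R - min(off)) / rho)
  diag(w) <- 0
  M <- m0 * w
  s <- max(rowSums(M))
  if (s > 0.5) M <- M * (0.5 / s)
  diag(M) <- 1 - rowSums(M)
  M
}

#' Forward Wright-Fisher simulation of genotypes under IBR
#'
#' Simulates allele frequencies in a stepping-stone system: each generation,
#' deterministic migration mixes deme frequencies (`F <- M F` per locus),
#' then multinomial drift resamples `2 Ne` gene copies per deme. After
#' `generations` steps, individuals are drawn per site with the configured
#' sample sizes, each genotype being two independent draws from the deme's
#' final frequencies.
#'
#' @param R_true pairwise effective-resistance matrix among the sites (the
#'   causal surface's circuit distances).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `table` (a `genotype_table`), `truth` (causal surface
#'   name, `R_true`, migration matrix, final per-deme frequency arrays).
#' @export
simulate_genotypes <- function(R_true, config, seed = 1L) {
  set.seed(seed)
  R_true <- as.matrix(R_true)
  P <- nrow(R_true)
  stopifnot(P == config$n_sites)
  sites <- rownames(R_true)
  if (is.null(sites)) sites <- sprintf("s%02d", seq_len(P))
  M <- migration_from_resistance(R_true, config$m0, config$rho)

  L <- config$n_loci
  founders <- founder_frequency_list(config)
  freqs <- vector("list", L)
  for (j in seq_len(L)) {
    f0 <- founders[[j]]
    Fm <- matrix(f0, P, length(f0), byrow = TRUE,
                 dimnames = list(sites, names(f0)))
    for (t in seq_len(config$generations)) {
      Fm <- M %*% Fm
      for (i in seq_len(P)) {
        Fm[i, ] <- stats::rmultinom(1, 2 * config$Ne, Fm[i, ]) /
          (2 * config$Ne)
      }
    }
    freqs[[j]] <- Fm
  }
  names(freqs) <- names(founders)

  sizes <- config$sample_sizes
  ids <- character(0); site_of <- character(0)
  a1 <- NULL; a2 <- NULL
  for (i in seq_len(P)) {
    n_i <- sizes[i]
    ids_i <- sprintf("%s_i%02d", sites[i], seq_len(n_i))
    g1 <- matrix(0L, n_i, L); g2 <- matrix(0L, n_i, L)
    for (j in seq_len(L)) {
      codes <- as.integer(colnames(freqs[[j]]))
      pr <- freqs[[j]][i, ]
      g1[, j] <- sample(codes, n_i, replace = TRUE, prob = pr)
      g2[, j] <- sample(codes, n_i, replace = TRUE, prob = pr)
    }
    ids <- c(ids, ids_i)
    site_of <- c(site_of, rep(sites[i], n_i))
    a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
  }
  tab <- genotype_table(ids, site_of, names(freqs), a1, a2)
  list(
    table = tab,
    truth = list(
      causal_class = config$causal_class,
      R_true = R_true,
      migration = M,
      final_freqs = freqs
    )
  )
}

founder_frequency_list <- function(config) {
  if (!is.null(config$founder_freqs)) {
    ff <- config$founder_freqs
    if (length(ff) < config$n_loci) {
      stop("founder_freqs must cover n_loci loci")
    }
    return(lapply(ff[seq_len(config$n_loci)], function(f) f / sum(f)))
  }
  k <- config$n_alleles
  codes <- as.character(100 + 2 * seq_len(k))  # dinucleotide-like ladder
  out <- lapply(seq_len(config$n_loci), function(j) {
    stats::setNames(rep(1 / k, k), codes)
  })
  names(out) <- sprintf("loc%d", seq_len(config$n_loci))
  out
}

#' Founding allele frequencies of an eight-locus microsatellite panel
#'
#' Average allele frequencies of a field-observed *Rana luteiventris*
#' (Columbia spotted frog) microsatellite panel of eight loci, shipped as a
#' plain-text table. Useful as realistic founder frequencies for
#' [simulate_genotypes()].
#'
#' @return named list of per-locus named frequency vectors (normalized).
#' @export
microsat_panel_freqs <- function() {
  path <- system.file("extdata", "microsat_panel_freqs.csv",
                      package = "ibrsamp")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$locus), function(d) {
    f <- stats::setNames(d$freq, as.character(d$allele))
    f <- f[f > 0]
    f / sum(f)
  })
  out[unique(df$locus)]
}

#' Generate a complete synthetic isolation-by-resistance study
#'
#' Runs the full generator: landscape, site placement, causal resistance
#' surface and its circuit distances, forward genetic simulation, and the
#' candidate predictor matrices (binary cover surfaces, raw slope and solar,
#' and the uniform isolation-by-distance layer), each as pairwise effective
#' resistance among the sites.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed; the landscape, placement, and genotype
#'   substreams are derived from it.
#' @param connectivity raster graph connectivity (4 or 8).
#' @return list with `landscape`, `nodes`, `predictors` (named list of
#'   [dist_matrix()]), `table`, `truth`, `config`, `seed`.
#' @export
simulate_ibr_study <- function(config = synthetic_config(), seed = 1L,
                               connectivity = 8) {
  land <- generate_landscape(config, seed = seed)
  nodes <- place_sites(land$cover, config$n_sites, config$min_sep,
                       seed = seed + 1L)
  nodes$site <- sprintf("s%02d", seq_len(nrow(nodes)))

  codes <- land$class_codes
  causal_code <- codes[[config$causal_class]]
  gen_surface <- land$cover
  gen_surface$values <- ifelse(land$cover$values == causal_code,
                               config$causal_resistance, 1)
  R_true <- effective_resistance(build_graph(gen_surface, connectivity),
                                 nodes)

  preds <- list()
  for (cl in names(codes)) {
    surf <- parameterize(land$cover, "binary_cover",
                         class_value = codes[[cl]])
    preds[[cl]] <- effective_resistance(build_graph(surf, connectivity),
                                        nodes)
  }
  preds$slope <- effective_resistance(
    build_graph(parameterize(land$slope, "raw"), connectivity), nodes
  )
  preds$solar <- effective_resistance(
    build_graph(parameterize(land$solar, "raw"), connectivity), nodes
  )
  preds$distance <- uniform_ibd_predictor(land$cover, nodes, connectivity)

  sim <- simulate_genotypes(unclass(R_true), config, seed = seed + 2L)
  list(
    landscape = land, nodes = nodes, predictors = preds,
    table = sim$table, truth = sim$truth, config = config, seed = seed
  )
}
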