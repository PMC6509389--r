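#' Construct a sampling-scheme dataset
#'
#' The three schemes differ in which sites and individuals enter the
#' analysis: `ISS` draws `n_per_site` individuals per site uniformly without
#' replacement (sites holding fewer contribute all of theirs); `PSS` keeps
#' all individuals at sites meeting `min_pop_size`; `PASS` keeps every
#' sampled individual at every site.
#'
#' @param x a `genotype_table`.
#' @param scheme `"ISS"`, `"PSS"`, or `"PASS"`.
#' @param sites site labels to draw from (default: all for ISS/PASS,
#'   population-level sites for PSS).
#' @param n_per_site individuals drawn per site (ISS only).
#' @param min_pop_size threshold used when `scheme = "PSS"` and `sites` is
#'   not given.
#' @param seed integer seed for the ISS draw (ignored for the deterministic
#'   PSS/PASS schemes).
#' @return a list with `table` (the subset `genotype_table`), `scheme`,
#'   `sites`, `n_per_site`, `seed`.
#' @export
make_scheme_dataset <- function(x, scheme = c("ISS", "PSS", "PASS"),
                                sites = NULL, n_per_site = 1,
                                min_pop_size = 11, seed = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(sites)) {
    sites <- if (scheme == "PSS") {
      classify_sites(x, min_pop_size)$population
    } else {
      unique(x$site)
    }
  }
  if (!length(sites)) stop("empty site set")
  if (scheme == "PSS") {
    counts <- site_counts(x)[sites]
    if (any(counts < min_pop_size)) {
      stop("PSS sites must all meet the minimum population size")
    }
  }
  if (scheme %in% c("PSS", "PASS")) {
    tab <- subset_genotypes(x, sites = sites)
    return(list(table = tab, scheme = scheme, sites = sites,
                n_per_site = NA_integer_, seed = NA_integer_))
  }
  stopifnot(n_per_site >= 1)
  if (!is.null(seed)) set.seed(seed)
  chosen <- unlist(lapply(sites, function(s) {
    ids <- x$id[x$site == s]
    if (length(ids) <= n_per_site) ids
    else sample(ids, n_per_site)
  }))
  list(table = subset_genotypes(x, individuals = chosen),
       scheme = "ISS", sites = sites,
       n_per_site = n_per_site,
       seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Bootstrap replicate experiment over per-site sample sizes
#'
#' For each sample size `n` in `n_values` and each of `R` replicates, draws
#' an ISS dataset (seeded `base_seed + r`, shared across `n`), computes the
#' population-averaged allele-sharing distance among `sites`, fits every
#' candidate model under each estimation method, and ranks by AICc and BIC.
#' Records, per (model, n, method, criterion): how often the model was
#' competitive (`delta < delta_threshold`) and the mean evidence weight with
#' its standard error over replicates.
#'
#' @param x a `genotype_table`.
#' @param sites site labels for this sampling density.
#' @param predictors named list of population-level resistance
#'   [dist_matrix()] objects covering at least `sites` (subset internally).
#' @param models [candidate_models()] list.
#' @param n_values integer vector of per-site sample sizes (default 1:11).
#' @param R replicates per sample size (default 100).
#' @param methods estimation methods to run.
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @param delta_threshold competitiveness cutoff on the criterion difference.
#' @return object of class `replicate_summary`: list with `summary` (a
#'   data.frame over model x n x method x criterion), `competitive_sets`
#'   (nested list of per-replicate competitive model names), and the run
#'   settings.
#' @export
run_replicates <- function(x, sites, predictors, models,
                           n_values = 1:11, R = 100,
                           methods = c("ML", "REML"),
                           base_seed = 1L, delta_threshold = 2) {
  stopifnot(R >= 1, all(n_values >= 1))
  methods <- match.arg(methods, c("ML", "REML"), several.ok = TRUE)
  preds <- lapply(predictors, function(p) {
    dist_matrix(unclass(p)[sites, sites], sites,
                metric = attr(p, "metric"), level = "population")
  })
  model_names <- vapply(models, `[[`, "", "name")
  crits <- c("AICc", "BIC")

  counts <- array(
    0L, dim = c(length(model_names), length(n_values), length(methods), 2),
    dimnames = list(model_names, as.character(n_values), methods, crits)
  )
  wsum <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  wsum2 <- wsum
  comp_sets <- list()

  # the pair->site incidence, hence eigen(ZZ'), is fixed by the site set
  P <- length(sites)
  Z0 <- matrix(0, P * (P - 1) / 2, P)
  idx0 <- which(lower.tri(matrix(0, P, P)), arr.ind = TRUE)
  Z0[cbind(seq_len(nrow(Z0)), idx0[, "row"])] <- 1
  Z0[cbind(seq_len(nrow(Z0)), idx0[, "col"])] <- 1
  eig <- eigen(tcrossprod(Z0), symmetric = TRUE)

  for (ni in seq_along(n_values)) {
    n <- n_values[ni]
    comp_sets[[as.character(n)]] <- list()
    for (r in seq_len(R)) {
      ds <- make_scheme_dataset(x, "ISS", sites = sites, n_per_site = n,
                                seed = base_seed + r)
      yq <- population_dps(ds$table)
      # reorder to the canonical site order
      yq <- dist_matrix(unclass(yq)[sites, sites], sites,
                        metric = "dps_distance", level = "population")
      rep_entry <- list()
      for (mi in seq_along(methods)) {
        sel <- fit_model_set(yq, preds, models, methods[mi], eig = eig)
        for (ci in 1:2) {
          tabk <- if (ci == 1) sel$aicc else sel$bic
          compet <- tabk$model[tabk$delta < delta_threshold]
          counts[tabk$model, ni, mi, ci] <-
            counts[tabk$model, ni, mi, ci] +
            as.integer(tabk$delta < delta_threshold)
          wsum[tabk$model, ni, mi, ci] <-
            wsum[tabk$model, ni, mi, ci] + tabk$weight
          wsum2[tabk$model, ni, mi, ci] <-
            wsum2[tabk$model, ni, mi, ci] + tabk$weight^2
          rep_entry[[paste(methods[mi], crits[ci], sep = ".")]] <- compet
        }
      }
      comp_sets[[as.character(n)]][[r]] <- rep_entry
    }
  }

  grid <- expand.grid(
    model = model_names, n_per_site = n_values, method = methods,
    criterion = crits, stringsAsFactors = FALSE
  )
  grid$n_competitive <- mapply(function(m, n, me, cr) {
    counts[m, as.character(n), me, cr]
  }, grid$model, grid$n_per_site, grid$method, grid$criterion)
  mw <- mapply(function(m, n, me, cr) {
    wsum[m, as.character(n), me, cr] / R
  }, grid$model, grid$n_per_site, grid$method, grid$criterion)
  m2 <- mapply(function(m, n, me, cr) {
    wsum2[m, as.character(n), me, cr] / R
  }, grid$model, grid$n_per_site, grid$method, grid$criterion)
  grid$mean_weight <- mw
  # SE of the mean: sample sd of weights over replicates / sqrt(R)
  grid$se_weight <- sqrt(pmax(m2 - mw^2, 0) * R / max(R - 1, 1)) / sqrt(R)
  grid$R <- R

  structure(list(
    summary = grid, competitive_sets = comp_sets,
    sites = sites, n_values = n_values, R = R, methods = methods,
    base_seed = base_seed, delta_threshold = delta_threshold
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> %d sites, n = %s, R = %d, methods: %s\n",
    length(x$sites), paste(range(x$n_values), collapse = "-"), x$R,
    paste(x$methods, collapse = "/")
  ))
  invisible(x)
}

#' Competitive model set from a replicate summary
#'
#' A model is competitive at a given sample size if its mean evidence weight
#' strictly exceeds `weight_threshold` or it was competitive
#' (`delta < 2`) in at least `count_threshold` of the replicates. The
#' default thresholds (0.1 and 30 of 100) are the usual convention for
#' summarizing bootstrap model-selection experiments.
#'
#' @param rs a `replicate_summary`.
#' @param n_per_site which sample size to read.
#' @param method `"ML"` or `"REML"`.
#' @param criterion `"AICc"` or `"BIC"`.
#' @param weight_threshold mean-weight cutoff (strict inequality).
#' @param count_threshold replicate-count cutoff (at least).
#' @return data.frame of admitted models with logical columns `by_weight`
#'   and `by_count` flagging which rule admitted each.
#' @export
competitive_models <- function(rs, n_per_site, method = "ML",
                               criterion = "AICc",
                               weight_threshold = 0.1,
                               count_threshold = 30) {
  stopifnot(weight_threshold > 0, count_threshold > 0)
  s <- rs$summary
  s <- s[s$n_per_site == n_per_site & s$method == method &
           s$criterion == criterion, ]
  by_w <- s$mean_weight > weight_threshold
  by_c <- s$n_competitive >= count_threshold
  out <- s[by_w | by_c, c("model", "n_competitive", "mean_weight")]
  out$by_weight <- by_w[by_w | by_c]
  out$by_count <- by_c[by_w | by_c]
  rownames(out) <- NULL
  out
}

#' Convergence of ISS model support toward a reference analysis
#'
#' For each per-site sample size, computes the fraction of replicates whose
#' competitive set (models with criterion difference below the replicate
#' threshold) agrees with a reference top-model set from a full-data (PSS or
#' PASS) analysis. Agreement is a nonempty intersection by default, or an
#' exact requirement that the replicate's single best support overlaps only
#' the reference (`mode = "subset"`: the competitive set must be contained
#' in the reference).
#'
#' @param rs a `replicate_summary`.
#' @param reference character vector of reference top-model names.
#' @param method,criterion which fits to read.
#' @param agreement_threshold fraction of replicates required (strict
#'   inequality, default 0.9).
#' @param mode `"intersect"` (default) or `"subset"`.
#' @return list with `fractions` (named by n), `converged_n` (minimal n with
#'   fraction strictly above the threshold, or `NA` if none).
#' @export
convergence_analysis <- function(rs, reference, method = "ML",
                                 criterion = "AICc",
                                 agreement_threshold = 0.9,
                                 mode = c("intersect", "subset")) {
  mode <- match.arg(mode)
  stopifnot(length(reference) >= 1)
  key <- paste(method, criterion, sep = ".")
  fr <- vapply(as.character(rs$n_values), function(nch) {
    reps <- rs$competitive_sets[[nch]]
    agree <- vapply(reps, function(e) {
      cs <- e[[key]]
      if (mode == "intersect") length(intersect(cs, reference)) > 0
      else length(cs) > 0 && all(cs %in% reference)
    }, logical(1))
    mean(agree)
  }, numeric(1))
  above <- which(fr > agreement_threshold)
  list(
    fractions = fr,
    converged_n = if (length(above)) rs$n_values[min(above)] else NA_integer_
  )
}
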