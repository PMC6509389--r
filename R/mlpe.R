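#' Build the pairwise response/design for an MLPE model
#'
#' One row per unordered site pair. The design matrix holds an intercept plus
#' the z-standardized lower-triangle vectors of the chosen resistance
#' predictors; the incidence matrix `Z` (pairs x sites) has a 1 for each of
#' the two endpoint sites of every pair, producing the MLPE covariance
#' structure in which pairs sharing a site are correlated.
#'
#' @param y population-level [dist_matrix()] response.
#' @param predictors named list of population-level [dist_matrix()]
#'   predictors with the same labels as `y`.
#' @param predictor_names character vector of predictor names for this model
#'   (may be empty for an intercept-only model).
#' @param standardize z-standardize predictor columns (default TRUE).
#' @return list with `y` (vector), `X` (matrix with intercept), `Z`
#'   (incidence matrix), `pairs` (data.frame `site_i`, `site_j`), `sites`.
#' @export
build_response_design <- function(y, predictors, predictor_names,
                                  standardize = TRUE) {
  sites <- rownames(y)
  for (nm in predictor_names) {
    if (!nm %in% names(predictors)) stop("unknown predictor: ", nm)
    if (!identical(rownames(predictors[[nm]]), sites)) {
      if (!all(sites %in% rownames(predictors[[nm]]))) {
        stop("label mismatch between response and predictor ", nm)
      }
      # predictor computed on a superset of sites: take the submatrix
      predictors[[nm]] <- dist_matrix(
        unclass(predictors[[nm]])[sites, sites], sites,
        metric = attr(predictors[[nm]], "metric"), level = "population"
      )
    }
  }
  P <- length(sites)
  idx <- which(lower.tri(matrix(0, P, P)), arr.ind = TRUE)
  n <- nrow(idx)
  Z <- matrix(0, n, P, dimnames = list(NULL, sites))
  Z[cbind(seq_len(n), idx[, "row"])] <- 1
  Z[cbind(seq_len(n), idx[, "col"])] <- 1
  X <- matrix(1, n, 1)
  for (nm in predictor_names) {
    v <- lower_triangle(predictors[[nm]])
    if (standardize) {
      s <- stats::sd(v)
      if (s == 0) stop("constant predictor: ", nm)
      v <- (v - mean(v)) / s
    }
    X <- cbind(X, v)
  }
  colnames(X) <- c("(Intercept)", predictor_names)
  list(
    y = lower_triangle(y), X = X, Z = Z,
    pairs = data.frame(site_i = sites[idx[, "row"]],
                       site_j = sites[idx[, "col"]]),
    sites = sites
  )
}

# profile log-likelihood machinery: V = sigma_e^2 (I + phi Z Z'), phi >= 0.
# Rotating by the eigenvectors Q of ZZ' diagonalizes V for every phi, so each
# phi evaluation is O(n p) after a one-off O(n^2 p) transform.
mlpe_profile <- function(ytil, Xtil, lam, phi, method) {
  w <- 1 + phi * lam
  n <- length(ytil)
  p <- ncol(Xtil)
  Xw <- Xtil / w
  XtWX <- crossprod(Xtil, Xw)
  XtWy <- crossprod(Xw, ytil)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  r <- ytil - Xtil %*% beta
  rss_w <- sum(r^2 / w)
  if (rss_w < 1e-290) {
    # degenerate exact fit (e.g. constant response): variance at the boundary
    return(list(ok = TRUE, beta = drop(beta), sigma_e2 = 0, loglik = Inf))
  }
  if (method == "ML") {
    sigma_e2 <- rss_w / n
    ll <- -0.5 * (n * log(2 * pi * sigma_e2) + sum(log(w)) + n)
  } else {
    sigma_e2 <- rss_w / (n - p)
    # log|X' V*^-1 X| with V* = I + phi ZZ'
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma_e2) + sum(log(w)) +
                    2 * sum(log(diag(ch))) + (n - p))
  }
  list(ok = TRUE, beta = drop(beta), sigma_e2 = sigma_e2, loglik = ll)
}

#' Fit an MLPE mixed model
#'
#' Gaussian mixed model for pairwise distances,
#' `y = X beta + Z u + e`, `u ~ N(0, sigma_u^2 I)` over sites,
#' `e ~ N(0, sigma_e^2 I)` over pairs, so
#' `V = sigma_e^2 I + sigma_u^2 Z Z'`. The likelihood is profiled over the
#' variance ratio `phi = sigma_u^2 / sigma_e^2`: given `phi`, `beta` is the
#' generalized-least-squares estimate and `sigma_e^2` is closed-form; `phi`
#' is maximized by bounded scalar search on `log(phi + eps)` from three
#' starting brackets, with the `phi = 0` boundary checked explicitly.
#'
#' @param y numeric response vector (one entry per site pair).
#' @param X design matrix including an intercept column.
#' @param Z pairs x sites incidence matrix (two unit entries per row; an
#'   all-zero `Z` degenerates to independent errors, i.e. OLS).
#' @param method `"ML"` or `"REML"`.
#' @param eig optional precomputed `eigen(tcrossprod(Z), symmetric = TRUE)`;
#'   the decomposition depends only on the site set, so callers fitting many
#'   models over the same pairs can share it.
#' @return an object of class `mlpe_fit`: list with `beta`, `sigma_u2`,
#'   `sigma_e2`, `phi`, `loglik`, `method`, `n_pairs`, `converged`.
#' @export
mlpe_fit <- function(y, X, Z, method = c("ML", "REML"), eig = NULL) {
  method <- match.arg(method)
  n <- length(y)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("design matrix is rank deficient")
  if (n <= ncol(X)) stop("need more pairs than fixed-effect parameters")

  if (is.null(eig)) eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  Q <- eig$vectors
  ytil <- drop(crossprod(Q, y))
  Xtil <- crossprod(Q, X)

  obj <- function(lphi) {
    res <- mlpe_profile(ytil, Xtil, lam, exp(lphi) - 1e-10, method)
    if (!res$ok) return(-Inf)
    res$loglik
  }
  best <- list(loglik = -Inf)
  converged <- TRUE
  cand_phi <- 1e-10
  for (bracket in list(c(-23, 0), c(-5, 5), c(0, 12))) {
    opt <- tryCatch(
      stats::optimize(obj, interval = bracket, maximum = TRUE,
                      tol = 1e-9),
      error = function(e) NULL
    )
    if (is.null(opt)) { converged <- FALSE; next }
    if (opt$objective > best$loglik + 0) {
      best <- list(loglik = opt$objective)
      cand_phi <- exp(opt$maximum) - 1e-10
    }
  }
  # boundary phi = 0 (no population effect)
  b0 <- mlpe_profile(ytil, Xtil, lam, 0, method)
  if (b0$ok && b0$loglik >= best$loglik) cand_phi <- 0

  phi <- max(cand_phi, 0)
  fin <- mlpe_profile(ytil, Xtil, lam, phi, method)
  if (!fin$ok) {
    return(structure(list(converged = FALSE, method = method, n_pairs = n),
                     class = "mlpe_fit"))
  }
  structure(list(
    beta = stats::setNames(fin$beta, colnames(X)),
    sigma_u2 = phi * fin$sigma_e2,
    sigma_e2 = fin$sigma_e2,
    phi = phi,
    loglik = fin$loglik,
    method = method,
    n_pairs = n,
    converged = converged
  ), class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("<mlpe_fit> %s, logLik %.4f, sigma_u2 %.5g, sigma_e2 %.5g\n",
              x$method, x$loglik, x$sigma_u2, x$sigma_e2))
  print(x$beta)
  invisible(x)
}

#' Small-sample information criteria
#'
#' `AICc = -2 l + 2k + 2k(k+1)/(n-k-1)` and `BIC = -2 l + k log(n)`, with
#' `n` the number of pairwise observations. The parameter count `k` follows
#' the convention intercept + slopes + two variance components, so a
#' single-predictor model has `k = 4`.
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count.
#' @param n effective sample size (number of pairs).
#' @return named numeric vector with `AICc` and `BIC`.
#' @export
information_criteria <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("n must exceed k + 1 for the AICc correction")
  c(
    AICc = -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1),
    BIC = -2 * loglik + k * log(n)
  )
}

#' Candidate model list
#'
#' @param singles character vector of predictor names, each defining a
#'   one-predictor model.
#' @param multis named list of character vectors for multi-predictor models.
#' @return list of models, each a list with `name`, `predictors`, `k`
#'   (`#predictors + 1 intercept + 2 variance components`).
#' @export
candidate_models <- function(singles, multis = list()) {
  mods <- lapply(singles, function(nm) {
    list(name = nm, predictors = nm, k = 1 + 1 + 2)
  })
  for (nm in names(multis)) {
    mods[[length(mods) + 1L]] <- list(
      name = nm, predictors = multis[[nm]], k = length(multis[[nm]]) + 3
    )
  }
  names(mods) <- vapply(mods, `[[`, "", "name")
  mods
}

#' Rank candidate models by an information criterion
#'
#' Computes differences to the best model and Akaike-type evidence weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Ties in delta
#' (within 1e-9) are broken by smaller `k`, then model name.
#'
#' @param ic numeric vector of criterion values (AICc or BIC), named by
#'   model.
#' @param k integer vector of parameter counts, same order.
#' @return data.frame with `model`, `k`, `ic`, `delta`, `weight`, `rank`,
#'   sorted best-first.
#' @export
rank_models <- function(ic, k = rep(NA_integer_, length(ic))) {
  stopifnot(length(ic) >= 1)
  nm <- names(ic)
  if (is.null(nm)) nm <- as.character(seq_along(ic))
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(round(delta / 1e-9) * 1e-9, k, nm)
  data.frame(
    model = nm, k = k, ic = ic, delta = delta, weight = w,
    rank = match(seq_along(ic), ord),
    row.names = NULL
  )[ord, , drop = FALSE]
}

#' Fit and rank a set of candidate MLPE models
#'
#' Fits every candidate model of a response distance matrix on resistance
#' predictors and returns AICc and BIC selection tables.
#'
#' @param y population-level [dist_matrix()] response.
#' @param predictors named list of predictor [dist_matrix()] objects.
#' @param models output of [candidate_models()].
#' @param method `"ML"` or `"REML"`.
#' @param eig optional shared eigendecomposition (see [mlpe_fit()]).
#' @return list with `fits` (named list of `mlpe_fit`), `aicc` and `bic`
#'   selection tables ([rank_models()] output), and `excluded` (names of any
#'   non-converged fits, dropped from ranking with a warning).
#' @export
fit_model_set <- function(y, predictors, models, method = c("ML", "REML"),
                          eig = NULL) {
  method <- match.arg(method)
  fits <- list(); aicc <- numeric(0); bic <- numeric(0); kk <- integer(0)
  excluded <- character(0)
  for (mod in models) {
    des <- build_response_design(y, predictors, mod$predictors)
    if (is.null(eig)) eig <- eigen(tcrossprod(des$Z), symmetric = TRUE)
    fit <- mlpe_fit(des$y, des$X, des$Z, method, eig = eig)
    fits[[mod$name]] <- fit
    if (!isTRUE(fit$converged)) {
      excluded <- c(excluded, mod$name)
      next
    }
    icv <- information_criteria(fit$loglik, mod$k, fit$n_pairs)
    aicc[mod$name] <- icv["AICc"]
    bic[mod$name] <- icv["BIC"]
    kk[mod$name] <- mod$k
  }
  if (length(excluded)) {
    warning("non-converged fits excluded from ranking: ",
            paste(excluded, collapse = ", "))
  }
  if (!length(aicc)) stop("no model converged")
  list(
    fits = fits,
    aicc = rank_models(aicc, kk),
    bic = rank_models(bic, kk),
    excluded = excluded
  )
}
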