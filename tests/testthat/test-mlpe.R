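test_that("the pairwise design has one row per unordered site pair", {
  P <- 3
  y <- dist_matrix(sym_from_lower(c(0.1, 0.2, 0.3), P))
  pred <- dist_matrix(sym_from_lower(c(1, 2, 3), P))
  des <- build_response_design(y, list(p = pred), "p")
  expect_equal(length(des$y), 3)
  expect_equal(nrow(des$X), 3)
  expect_equal(unname(rowSums(des$Z)), rep(2, 3))

  # 18 sites -> 153 rows; 40 sites -> 780 rows
  for (P in c(18, 40)) {
    n <- P * (P - 1) / 2
    yb <- dist_matrix(sym_from_lower(runif(n), P))
    pb <- dist_matrix(sym_from_lower(runif(n) + 1, P))
    d <- build_response_design(yb, list(p = pb), "p")
    expect_equal(length(d$y), n)
    # standardized predictor columns: mean 0, sd 1
    expect_equal(mean(d$X[, "p"]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(d$X[, "p"]), 1, tolerance = 1e-12)
  }

  expect_error(build_response_design(y, list(p = pred), "nope"),
               "unknown predictor")
})

test_that("MLPE likelihoods match the dense multivariate-normal oracle", {
  skip_if_not_installed("MASS")
  set.seed(14)
  for (P in c(4, 6, 8)) {
    n <- P * (P - 1) / 2
    y <- dist_matrix(sym_from_lower(runif(n, 0.3, 0.9), P))
    pred <- dist_matrix(sym_from_lower(runif(n, 1, 5), P))
    des <- build_response_design(y, list(p = pred), "p")
    # inject genuine site effects so phi-hat is interior
    u <- rnorm(P, 0, 0.15)
    yy <- des$y + drop(des$Z %*% u)
    for (method in c("ML", "REML")) {
      fit <- mlpe_fit(yy, des$X, des$Z, method)
      orc <- mlpe_grid_oracle(yy, des$X, des$Z, method)
      expect_true(fit$converged)
      expect_gte(fit$loglik, orc$loglik - 1e-6)
      expect_equal(fit$loglik, orc$loglik, tolerance = 1e-4)
      expect_equal(fit$phi, orc$phi, tolerance = 2e-3)
    }
  }
})

test_that("independence structure degenerates MLPE to ordinary least squares", {
  set.seed(15)
  P <- 10
  n <- P * (P - 1) / 2
  y <- dist_matrix(sym_from_lower(runif(n), P))
  pred <- dist_matrix(sym_from_lower(runif(n, 1, 3), P))
  des <- build_response_design(y, list(p = pred), "p")

  # zeroed incidence: GLS = OLS exactly
  Z0 <- des$Z * 0
  fit0 <- mlpe_fit(des$y, des$X, Z0, "ML")
  ols <- stats::lm(des$y ~ des$X - 1)
  expect_equal(unname(fit0$beta), unname(stats::coef(ols)),
               tolerance = 1e-8)

  # data simulated with sigma_u^2 = 0: phi-hat near 0, beta near OLS
  yy <- 0.4 + 0.08 * des$X[, 2] + rnorm(n, 0, 0.05)
  fit <- mlpe_fit(yy, des$X, des$Z, "ML")
  olsy <- stats::lm(yy ~ des$X - 1)
  se <- sqrt(diag(stats::vcov(olsy)))
  expect_lt(fit$sigma_u2 / fit$sigma_e2, 0.2)
  expect_true(all(abs(fit$beta - stats::coef(olsy)) < 2 * se))
})

test_that("REML is invariant to response shifts; constant responses are safe", {
  set.seed(16)
  P <- 8
  n <- P * (P - 1) / 2
  pred <- dist_matrix(sym_from_lower(runif(n, 1, 5), P))
  y <- dist_matrix(sym_from_lower(runif(n), P))
  des <- build_response_design(y, list(p = pred), "p")
  u <- rnorm(P, 0, 0.1)
  yy <- des$y + drop(des$Z %*% u)
  f1 <- mlpe_fit(yy, des$X, des$Z, "REML")
  f2 <- mlpe_fit(yy + 7, des$X, des$Z, "REML")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$sigma_u2, f2$sigma_u2, tolerance = 1e-6)

  fc <- mlpe_fit(rep(0.5, n), des$X, des$Z, "ML")
  expect_equal(unname(fc$beta[2]), 0, tolerance = 1e-10)
  expect_equal(fc$sigma_e2, 0)
})

test_that("profile optimization recovers an interior variance ratio", {
  # generative model with known phi; compare to a fine grid oracle
  skip_if_not_installed("MASS")
  set.seed(17)
  P <- 12
  n <- P * (P - 1) / 2
  pred <- dist_matrix(sym_from_lower(runif(n, 1, 5), P))
  des <- build_response_design(dist_matrix(sym_from_lower(runif(n), P)),
                               list(p = pred), "p")
  yy <- 0.5 + 0.1 * des$X[, 2] + drop(des$Z %*% rnorm(P, 0, 0.2)) +
    rnorm(n, 0, 0.1)
  for (method in c("ML", "REML")) {
    fit <- mlpe_fit(yy, des$X, des$Z, method)
    orc <- mlpe_grid_oracle(yy, des$X, des$Z, method)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-5)
    expect_gt(fit$sigma_u2, 0)
  }
})

test_that("information criteria reproduce hand arithmetic", {
  ic <- information_criteria(-10, k = 4, n = 153)
  expect_equal(unname(ic["AICc"]), 28 + 40 / 148, tolerance = 1e-10)
  expect_equal(unname(ic["BIC"]), 20 + 4 * log(153), tolerance = 1e-10)

  # AICc approaches AIC as n grows
  big <- information_criteria(-10, 4, 1e7)
  expect_equal(unname(big["AICc"]), 28, tolerance = 1e-4)

  # smaller k at equal loglik wins on both criteria
  ic4 <- information_criteria(-10, 4, 100)
  ic5 <- information_criteria(-10, 5, 100)
  expect_lt(ic4["AICc"], ic5["AICc"])
  expect_lt(ic4["BIC"], ic5["BIC"])
  expect_error(information_criteria(-10, 10, 11), "exceed")
})

test_that("the parameter-count convention matches model structure", {
  mods <- candidate_models(
    c("forest_ld", "distance"),
    multis = list(fullest = c("grass", "forest_ld", "forest_hd", "slope"))
  )
  expect_equal(mods[["distance"]]$k, 4)   # 1 slope + intercept + 2 var comp
  expect_equal(mods[["forest_ld"]]$k, 4)
  expect_equal(mods[["fullest"]]$k, 7)    # 4 slopes + intercept + 2 var comp
})

test_that("model ranking produces normalized monotone weights", {
  tab <- rank_models(c(m1 = 100, m2 = 102), k = c(4L, 5L))
  expect_equal(tab$delta, c(0, 2))
  expect_equal(tab$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-10)

  single <- rank_models(c(only = 50), k = 4L)
  expect_equal(single$delta, 0)
  expect_equal(single$weight, 1)

  # permuting input order permutes rows only
  ic <- c(a = 11, b = 10, c = 13)
  t1 <- rank_models(ic, c(4L, 4L, 5L))
  t2 <- rank_models(ic[c(3, 1, 2)], c(5L, 4L, 4L))
  expect_equal(t1$model, t2$model)
  expect_equal(t1$weight, t2$weight, tolerance = 1e-12)

  # ties broken by smaller k then name
  t3 <- rank_models(c(zed = 10, ann = 10), k = c(5L, 4L))
  expect_equal(t3$model, c("ann", "zed"))
})

test_that("fitting a model set on synthetic data ranks the causal surface", {
  study <- cached_small_study()
  y <- population_dps(study$table)
  models <- candidate_models(names(study$predictors))
  sel <- fit_model_set(y, study$predictors, models, "ML")
  expect_setequal(sel$aicc$model, names(study$predictors))
  expect_equal(sum(sel$aicc$weight), 1, tolerance = 1e-10)
  expect_equal(min(sel$aicc$delta), 0)
  # weights decrease along increasing delta
  expect_true(all(diff(sel$aicc$weight[order(sel$aicc$delta)]) <= 1e-12))
})
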