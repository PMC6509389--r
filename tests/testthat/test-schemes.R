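test_that("scheme datasets respect their defining rules", {
  tab <- random_table(n_ind = 40, n_sites = 5, seed = 20)

  pass <- make_scheme_dataset(tab, "PASS")
  expect_equal(sort(pass$table$id), sort(tab$id))

  iss1 <- make_scheme_dataset(tab, "ISS", n_per_site = 1, seed = 3)
  expect_equal(n_individuals(iss1$table), length(unique(tab$site)))
  expect_equal(unname(site_counts(iss1$table)),
               rep(1L, length(unique(tab$site))))

  # a site holding exactly n_per_site individuals is fully included
  counts <- site_counts(tab)
  full_site <- names(counts)[1]
  issf <- make_scheme_dataset(tab, "ISS", n_per_site = counts[full_site],
                              seed = 99)
  expect_setequal(
    issf$table$id[issf$table$site == full_site],
    tab$id[tab$site == full_site]
  )

  # ISS draws are without replacement and reproducible under the seed
  a <- make_scheme_dataset(tab, "ISS", n_per_site = 3, seed = 11)
  b <- make_scheme_dataset(tab, "ISS", n_per_site = 3, seed = 11)
  expect_identical(a$table$id, b$table$id)
  expect_false(anyDuplicated(a$table$id) > 0)

  # PSS refuses sites below the threshold
  expect_error(
    make_scheme_dataset(tab, "PSS", sites = unique(tab$site),
                        min_pop_size = 100),
    "minimum population size"
  )
  expect_error(make_scheme_dataset(tab, "ISS", sites = character(0)),
               "empty site set")
})

test_that("replicate summaries are reproducible and bounded", {
  study <- cached_small_study()
  cls <- classify_sites(study$table, 11)
  models <- candidate_models(c("forest_ld", "grass", "distance"))
  rs1 <- run_replicates(study$table, cls$population, study$predictors,
                        models, n_values = c(1, 3), R = 4,
                        methods = "ML", base_seed = 5)
  rs2 <- run_replicates(study$table, cls$population, study$predictors,
                        models, n_values = c(1, 3), R = 4,
                        methods = "ML", base_seed = 5)
  expect_identical(rs1$summary, rs2$summary)

  s <- rs1$summary
  expect_true(all(s$n_competitive >= 0 & s$n_competitive <= 4))
  expect_true(all(s$mean_weight >= 0 & s$mean_weight <= 1))
  expect_true(all(s$se_weight >= 0))
  # weights over models sum to 1 in every cell of the grid
  agg <- stats::aggregate(mean_weight ~ n_per_site + method + criterion,
                          data = s, FUN = sum)
  expect_equal(agg$mean_weight, rep(1, nrow(agg)), tolerance = 1e-8)
})

test_that("drawing every individual reproduces the deterministic analysis", {
  study <- cached_small_study()
  cls <- classify_sites(study$table, 11)
  sites <- cls$population
  models <- candidate_models(c("forest_ld", "distance"))
  nmax <- max(site_counts(study$table)[sites])
  rs <- run_replicates(study$table, sites, study$predictors, models,
                       n_values = nmax, R = 2, methods = "ML",
                       base_seed = 1)
  # both replicates saw the full data: counts are 0 or R, SE of weights 0
  s <- rs$summary[rs$summary$criterion == "AICc", ]
  expect_true(all(s$n_competitive %in% c(0L, 2L)))
  expect_equal(s$se_weight, rep(0, nrow(s)), tolerance = 1e-12)

  # and the weights equal the deterministic PSS fit
  y <- population_dps(subset_genotypes(study$table, sites = sites))
  sel <- fit_model_set(y, study$predictors, models, "ML")
  for (m in s$model) {
    expect_equal(s$mean_weight[s$model == m],
                 sel$aicc$weight[sel$aicc$model == m], tolerance = 1e-9)
  }
})

test_that("competitive-set rules apply strict weight and count thresholds", {
  fake <- list(summary = data.frame(
    model = c("a", "b", "c"), n_per_site = 1, method = "ML",
    criterion = "AICc", n_competitive = c(50L, 30L, 10L),
    mean_weight = c(0.7, 0.2, 0.1), se_weight = 0, R = 100L
  ))
  out <- competitive_models(fake, 1, "ML", "AICc",
                            weight_threshold = 0.1, count_threshold = 30)
  # weight 0.1 is excluded by the strict rule; count 30 is included
  expect_setequal(out$model, c("a", "b"))
  expect_true(all(out$by_weight[out$model == "a"]))
  expect_true(out$by_count[out$model == "b"])

  # equal weights across many models fall below the threshold
  fake2 <- list(summary = data.frame(
    model = sprintf("m%d", 1:17), n_per_site = 1, method = "ML",
    criterion = "AICc", n_competitive = 0L,
    mean_weight = rep(1 / 17, 17), se_weight = 0, R = 100L
  ))
  out2 <- competitive_models(fake2, 1, "ML", "AICc", 0.1, 30)
  expect_equal(nrow(out2), 0)
})

test_that("convergence analysis finds the smallest agreeing sample size", {
  mk_sets <- function(fracs, ns = seq_along(fracs)) {
    # build competitive_sets where a fraction of replicates contain "ref"
    out <- list()
    for (i in seq_along(fracs)) {
      n_agree <- round(fracs[i] * 10)
      out[[as.character(ns[i])]] <- lapply(1:10, function(r) {
        list(ML.AICc = if (r <= n_agree) c("ref", "other") else "other")
      })
    }
    out
  }
  rs <- list(n_values = 1:3, competitive_sets = mk_sets(c(0.5, 0.8, 1.0)))
  cv <- convergence_analysis(rs, "ref", "ML", "AICc", 0.9)
  expect_equal(unname(cv$fractions), c(0.5, 0.8, 1.0))
  expect_equal(cv$converged_n, 3)

  # reference competitive everywhere -> smallest tested n
  rs2 <- list(n_values = 2:4, competitive_sets = mk_sets(c(1, 1, 1), 2:4))
  expect_equal(convergence_analysis(rs2, "ref")$converged_n, 2)

  # never above threshold -> NA
  rs3 <- list(n_values = 1:2, competitive_sets = mk_sets(c(0.1, 0.4)))
  expect_true(is.na(convergence_analysis(rs3, "ref")$converged_n))

  # subset mode demands containment in the reference
  cv4 <- convergence_analysis(rs, c("ref", "other"), mode = "subset")
  expect_equal(unname(cv4$fractions), c(1, 1, 1))
  cv5 <- convergence_analysis(rs, "ref", mode = "subset")
  expect_equal(unname(cv5$fractions), c(0, 0, 0))
})
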