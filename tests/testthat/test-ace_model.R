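params_for <- function(A, C, rcdos = 1, K = 2,
                       cohorts = c("c1", "c2")[seq_len(K)]) {
  ace_params(matrix(A, 2, K), matrix(C, 2, K), matrix(1 - A - C, 2, K),
             rcdos, array(0, c(2, 2, K)), cohorts)
}

test_that("implied correlations follow the ACE covariance algebra", {
  p <- params_for(A = 1, C = 0)
  expect_equal(implied_correlation(p, "MZM", "c1"), 1)
  expect_equal(implied_correlation(p, "DZM", "c1"), 0.5)
  # combined-cohort male shares: A = .66, C = .14 imply rMZ .80, rDZ .47
  p <- params_for(A = 0.66, C = 0.14)
  expect_equal(implied_correlation(p, "MZM", "c1"), 0.80)
  expect_equal(implied_correlation(p, "DZM", "c1"), 0.47)
  # symmetric sexes with rcdos = 1: DOS equals same-sex DZ
  expect_equal(implied_correlation(p, "DOS", "c1"),
               implied_correlation(p, "DZF", "c1"))
  # rcdos scales only the shared-environment cross term
  p2 <- params_for(A = 0.66, C = 0.14, rcdos = 0)
  expect_equal(implied_correlation(p2, "DOS", "c1"), 0.5 * 0.66)
})

test_that("pair log-likelihood handles pairs, singletons and zero cells", {
  p <- params_for(A = 1, C = 0, K = 1, cohorts = "c1")
  rec <- list(group = "MZM", cohort = "c1", pheno1 = 1L, pheno2 = 1L)
  expect_equal(pair_loglik(rec, p), log(0.5), tolerance = 1e-9)
  rec$pheno2 <- 0L  # impossible under r = 1
  ll <- pair_loglik(rec, p)
  expect_lt(ll, log(1e-250))
  # singleton margin at the threshold for 22.8% prevalence
  p$tau["M", "MZ", "c1"] <- 0.74544949
  rec <- list(group = "MZM", cohort = "c1", pheno1 = 1L,
              pheno2 = NA_integer_)
  expect_equal(pair_loglik(rec, p), log(0.228), tolerance = 1e-6)
})

test_that("model df reproduces the printed ladder bookkeeping", {
  expected <- c(4990, 4992, 4995, 4995, 4998, 5001, 5002, 5002)
  dfs <- vapply(1:8, function(id) model_df(ace_model_spec(id), 5008),
                numeric(1))
  expect_equal(dfs, expected)
  # free-parameter counts behind them
  expect_equal(ace_model_spec(1)$n_free_params, 22)
  expect_equal(ace_model_spec(6)$n_free_params, 11)
  # generic arithmetic: saturated-correlation style accounting
  expect_equal(model_df(list(n_free_params = 13, n_constraint_equations = 0),
                        5008), 4995)
})

test_that("saturated FIML fit equals per-group tetrachoric estimates", {
  counts <- data.frame(cohort = "c",
                       group = c("MZM", "DZM", "MZF", "DZF", "DOS"),
                       n_pairs = 400, n_singletons = 0)
  prevalence <- data.frame(cohort = "c", sex = c("M", "M", "F", "F"),
                           zygosity = rep(c("MZ", "DZ"), 2),
                           prev = c(0.45, 0.5, 0.35, 0.42))
  cfg <- sim_config("c", counts, prevalence, A = 0.5, C = 0.3, E = 0.2)
  ds <- simulate_twins(cfg, seed = 11)
  sat <- fit_saturated(ds)
  for (g in c("MZM", "DZM", "MZF", "DZF", "DOS")) {
    et <- estimate_tetrachoric(concordance_table(ds, g),
                               share_threshold = g != "DOS", ci = FALSE)
    expect_equal(sat$correlations$r[sat$correlations$group == g], et$r,
                 tolerance = 1e-4)
  }
})

test_that("sub-model deviances never beat their parents", {
  ds <- simulate_twins(scaled_preset(0.6), seed = 17)
  fits <- list()
  for (id in 1:8) {
    parent <- c(NA, 1, 2, 2, 2, 5, 6, 6)[id]
    warm <- if (!is.na(parent)) fits[[parent]]$params else NULL
    fits[[id]] <- fit_ace(ds, ace_model_spec(id), start = warm, n_starts = 1)
  }
  for (id in 2:8) {
    parent <- c(NA, 1, 2, 2, 2, 5, 6, 6)[id]
    expect_gte(fits[[id]]$minus2LL, fits[[parent]]$minus2LL - 1e-6)
  }
  # unit-variance constraint holds in every fitted cell
  for (f in fits) {
    expect_lt(max(abs(f$shares$A + f$shares$C + f$shares$E - 1)), 1e-8)
  }
})

test_that("implied fitted correlation sits between DZ and MZ tetrachorics", {
  cfg <- scaled_preset(1)
  ds <- simulate_twins(cfg, seed = 23)
  f6 <- fit_ace(ds, ace_model_spec(6), n_starts = 2)
  rmz <- implied_correlation(f6$params, "MZM", "1993-1995")
  rdz <- implied_correlation(f6$params, "DZM", "1993-1995")
  tmz <- estimate_tetrachoric(concordance_table(ds, "MZM"), ci = TRUE)
  tdz <- estimate_tetrachoric(concordance_table(ds, "DZM"), ci = TRUE)
  expect_gt(rmz, tdz$ci_low)
  expect_lt(rmz, tmz$ci_high)
  expect_gt(rdz, tdz$ci_low)
  expect_lt(rdz, tmz$ci_high)
})

test_that("profile CI truncates at zero for an absent component", {
  counts <- data.frame(cohort = "c",
                       group = c("MZM", "DZM", "MZF", "DZF", "DOS"),
                       n_pairs = 3000, n_singletons = 0)
  prevalence <- data.frame(cohort = "c", sex = c("M", "M", "F", "F"),
                           zygosity = rep(c("MZ", "DZ"), 2), prev = 0.4)
  cfg <- sim_config("c", counts, prevalence, A = 0.5, C = 0, E = 0.5)
  ds <- simulate_twins(cfg, seed = 31)
  spec <- ace_model_spec(6, n_cohorts = 1)
  f <- fit_ace(ds, spec, n_starts = 2)
  ci_c <- profile_ci(f, "C", cohort = "c")
  expect_equal(ci_c[1], 0)
  # E interval excludes zero whenever MZ discordance is present
  expect_gt(sum(ds$pheno1 != ds$pheno2 & ds$group == "MZM", na.rm = TRUE), 0)
  ci_e <- profile_ci(f, "E", cohort = "c")
  expect_gt(ci_e[1], 0)
})
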