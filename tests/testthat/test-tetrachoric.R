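test_that("concordance tables tabulate pairs, singletons and pooling", {
  recs <- data.frame(
    family_id = paste0("f", 1:4), group = "MZM",
    cohort = c("c1", "c1", "c1", "c2"),
    pheno1 = c(1L, 1L, 0L, 1L), pheno2 = c(1L, 0L, 0L, NA_integer_),
    stringsAsFactors = FALSE)
  ds <- twin_dataset(recs)
  tab <- concordance_table(ds, "MZM", "c1")
  expect_equal(unlist(tab[c("n11", "n10", "n01", "n00")]),
               c(n11 = 1, n10 = 1, n01 = 0, n00 = 1))
  tab2 <- concordance_table(ds, "MZM", "c2")
  expect_equal(tab2$s1a, 1)
  expect_equal(tab2$n11 + tab2$n10 + tab2$n01 + tab2$n00, 0)
  pooled <- concordance_table(ds, "MZM", "combined")
  for (f in c("n11", "n10", "n01", "n00", "s1a", "s1u", "s2a", "s2u")) {
    expect_equal(pooled[[f]], tab[[f]] + tab2[[f]])
  }
  expect_error(concordance_table(ds, "DOS"), "no records")
})

test_that("independence counts give r = 0 and zero thresholds", {
  fit <- estimate_tetrachoric(concordance_counts(250, 250, 250, 250),
                              ci = FALSE)
  expect_equal(fit$r, 0, tolerance = 1e-6)
  expect_equal(fit$tau1, 0, tolerance = 1e-6)
})

test_that("estimator recovers the generating cell probabilities exactly", {
  p <- cell_probabilities(0.5, 0.5, 0.6)
  tab <- concordance_counts(1000 * p$p11, 1000 * p$p10,
                            1000 * p$p01, 1000 * p$p00)
  fit <- estimate_tetrachoric(tab, ci = FALSE)
  expect_equal(fit$r, 0.6, tolerance = 1e-3)
  expect_equal(fit$tau1, 0.5, tolerance = 1e-3)
})

test_that("optimizer matches the brute-force profile grid search", {
  set.seed(101)
  for (i in 1:5) {
    tab <- draw_table(500, runif(1, -0.8, 0.8), runif(1, -0.8, 0.8))
    fit <- estimate_tetrachoric(tab, ci = FALSE)
    oracle <- grid_tetrachoric_oracle(tab)
    expect_lt(abs(fit$r - oracle$r), 1.5e-3)
    expect_lte(fit$minus2LL, oracle$dev + 1e-6)
  }
})

test_that("degenerate concordant tables return a flagged boundary fit", {
  fit <- estimate_tetrachoric(concordance_counts(40, 0, 0, 60), ci = FALSE)
  expect_true(fit$boundary)
  expect_gt(fit$r, 0.99)
})

test_that("estimator is consistent across true correlations", {
  set.seed(202)
  for (r_true in c(0.4, 0.67, 0.8)) {
    errs <- vapply(1:30, function(i) {
      fit <- estimate_tetrachoric(draw_table(5000, r_true, 0.25), ci = FALSE)
      abs(fit$r - r_true)
    }, numeric(1))
    expect_lt(mean(errs), 0.02)
  }
})

test_that("profile CI covers the true correlation at nominal rate", {
  set.seed(303)
  nrep <- 500
  cover <- 0
  for (i in 1:nrep) {
    tab <- draw_table(300, 0.5, 0.25)
    fit <- estimate_tetrachoric(tab)
    cover <- cover + (fit$ci_low <= 0.5 && 0.5 <= fit$ci_high)
  }
  expect_gte(cover / nrep, 0.93)
  expect_lte(cover / nrep, 0.97)
})

test_that("correlation table: single cohort combined equals the cohort", {
  counts <- data.frame(cohort = "c",
                       group = c("MZM", "DZM", "MZF", "DZF", "DOS"),
                       n_pairs = 300, n_singletons = 5)
  prevalence <- data.frame(cohort = "c", sex = c("M", "M", "F", "F"),
                           zygosity = rep(c("MZ", "DZ"), 2), prev = 0.4)
  cfg <- sim_config("c", counts, prevalence, A = 0.5, C = 0.3, E = 0.2)
  ds <- simulate_twins(cfg, seed = 21)
  tab <- correlation_table(ds, ci = FALSE)
  for (g in c("MZM", "DZF")) {
    expect_equal(tab$r[tab$group == g & tab$cohort == "combined"],
                 tab$r[tab$group == g & tab$cohort == "c"])
  }
  # genetic signal: MZ exceeds DZ within sex on a2 > 0 data
  r_of <- function(g) tab$r[tab$group == g & tab$cohort == "combined"]
  expect_gt(r_of("MZM"), r_of("DZM"))
  expect_gt(r_of("MZF"), r_of("DZF"))
})

test_that("two-cohort combined column recovers a shared correlation", {
  cfg <- scaled_preset(1)
  ds <- simulate_twins(cfg, seed = 33)
  tab <- correlation_table(ds, ci = TRUE)
  # generating structure: rho_MZ = .78, rho_DZ = .505 in both cohorts
  mzm <- tab[tab$group == "MZM" & tab$cohort == "combined", ]
  expect_lt(abs(mzm$r - 0.78), 0.08)
  expect_true(mzm$ci_low <= 0.78 && 0.78 <= mzm$ci_high)
  dzf <- tab[tab$group == "DZF" & tab$cohort == "combined", ]
  expect_lt(abs(dzf$r - 0.505), 0.15)
  fmt <- format_correlation_table(tab)
  expect_match(fmt$ci[fmt$group == "MZM" & fmt$cohort == "combined"],
               "^-?\\d\\.\\d{2} - -?\\d\\.\\d{2}$")
})
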