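make_records <- function(...) {
  do.call(rbind, lapply(list(...), function(x) {
    data.frame(family_id = x[[1]], group = x[[2]], cohort = x[[3]],
               pheno1 = x[[4]], pheno2 = x[[5]], stringsAsFactors = FALSE)
  }))
}

test_that("dataset counting: pairs count twice, singletons once", {
  ds <- twin_dataset(make_records(
    list("f1", "MZM", "c1", 1L, 0L),
    list("f2", "MZM", "c1", 1L, 1L),
    list("f3", "DZF", "c1", 0L, NA_integer_)))
  expect_equal(nrow(ds), 3)
  expect_equal(n_individuals(ds), 5)
})

test_that("validation rejects bad groups, empty rows and bad phenotypes", {
  good <- make_records(list("f1", "MZM", "c1", 1L, 0L))
  expect_error(twin_dataset(rbind(good, make_records(
    list("f2", "XX", "c1", 1L, 0L)))), "unknown group")
  expect_error(twin_dataset(make_records(
    list("f1", "MZM", "c1", NA_integer_, NA_integer_))), "missing")
  expect_error(twin_dataset(make_records(
    list("f1", "MZM", "c1", 2L, 0L))), "phenotype")
  expect_error(twin_dataset(good[, -2]), "required column")
})

test_that("CSV reader excludes and counts invalid rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("family_id,group,cohort,pheno1,pheno2",
               "f1,MZM,c1,1,0",
               "f2,XX,c1,1,0",
               "f3,DZF,c1,,",
               "f4,DOS,c1,0,1"), path)
  expect_warning(
    expect_message(ds <- read_twin_dataset(path), "excluded 1 row"),
    "both phenotypes missing")
  expect_equal(nrow(ds), 2)
  expect_equal(attr(ds, "n_excluded_group"), 1)
  expect_equal(attr(ds, "n_excluded_missing"), 1)
})

test_that("write/read round trip preserves the dataset", {
  cfg <- scaled_preset(0.1)
  ds <- simulate_twins(cfg, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_twin_dataset(ds, path)
  ds2 <- read_twin_dataset(path)
  expect_equal(as.data.frame(ds), as.data.frame(ds2), ignore_attr = TRUE)
  expect_equal(attr(ds, "cohorts"), attr(ds2, "cohorts"))
})

test_that("DOS rows with female-first sex columns are normalized", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("family_id,group,cohort,pheno1,pheno2,sex1,sex2",
               "f1,DOS,c1,1,0,F,M"), path)
  ds <- read_twin_dataset(path)
  expect_equal(ds$pheno1, 0L)  # male slot
  expect_equal(ds$pheno2, 1L)
})

test_that("prevalence table reproduces printed-count percentages", {
  ds <- table1_dataset()
  tab <- prevalence_table(ds)
  cell <- function(cohort, sex, cls) {
    tab[tab$cohort == cohort & tab$sex == sex & tab$zygosity_class == cls, ]
  }
  t93m <- cell("1993-1995", "M", "Total")
  expect_equal(t93m$n_total, 1162)
  expect_equal(t93m$n_ever, 592)
  expect_equal(t93m$pct, 50.9)
  expect_equal(cell("2009-2010", "M", "Total")$pct, 22.8)
  expect_equal(cell("2009-2010", "F", "Total")$pct, 22.4)
  expect_equal(cell("1993-1995", "F", "Total")$pct, 39.5)
  expect_equal(cell("1993-1995", "M", "MZ")$pct, 45.8)
  expect_equal(cell("2009-2010", "F", "DZos")$pct, 25.5)
  # cohort cell totals add up to the cohort individual count
  for (k in attr(ds, "cohorts")) {
    tot <- sum(tab$n_total[tab$cohort == k & tab$zygosity_class == "Total"])
    sub <- ds[ds$cohort == k, ]
    expect_equal(tot, sum(!is.na(sub$pheno1)) + sum(!is.na(sub$pheno2)))
  }
})

test_that("all-unaffected dataset gives zero percentages", {
  ds <- twin_dataset(make_records(
    list("f1", "MZM", "c1", 0L, 0L),
    list("f2", "DZF", "c1", 0L, 0L)))
  expect_true(all(prevalence_table(ds)$pct == 0))
})

test_that("prevalence comparison flags the printed cohort differences", {
  ds <- table1_dataset()
  res <- compare_prevalence(ds, "cohort", sex = "M")
  expect_equal(res$prop, unname(c(592 / 1162, 175 / 768)),
               ignore_attr = TRUE)
  expect_lt(res$p_pearson, 0.001)
  expect_lt(res$p_lrt, 0.001)
  res <- compare_prevalence(ds, "zygosity", sex = "M", cohort = "2009-2010")
  expect_equal(sum(res$prop * c(301, 239 + 228)), 44 + 69 + 62)
  expect_lt(res$p_pearson, 0.001)
})

test_that("identical proportions give a zero statistic and p = 1", {
  res <- prevalence_test(c(30, 60), c(100, 200))
  expect_equal(res$chisq, 0)
  expect_equal(res$p_pearson, 1)
  expect_equal(res$lrt, 0)
  expect_error(prevalence_test(c(1, 1), c(0, 10)))
})

test_that("Pearson and threshold-LRT decisions agree on null data", {
  set.seed(314)
  agree <- 0
  for (i in 1:200) {
    ever <- rbinom(2, size = c(500, 400), prob = 0.3)
    res <- prevalence_test(ever, c(500, 400))
    agree <- agree + ((res$p_pearson < 0.01) == (res$p_lrt < 0.01))
  }
  expect_gte(agree / 200, 0.95)
})

test_that("simulated prevalences converge to the configured cells", {
  n <- 1e5
  counts <- data.frame(cohort = "c", group = c("MZM", "MZF"),
                       n_pairs = c(n / 2, n / 2), n_singletons = 0)
  prevalence <- data.frame(cohort = "c", sex = c("M", "M", "F", "F"),
                           zygosity = rep(c("MZ", "DZ"), 2),
                           prev = c(0.3, 0.3, 0.45, 0.45))
  cfg <- sim_config("c", counts, prevalence, A = 0.5, C = 0.2, E = 0.3)
  ds <- simulate_twins(cfg, seed = 99)
  tab <- prevalence_table(ds)
  pm <- tab[tab$sex == "M" & tab$zygosity_class == "MZ", ]
  pf <- tab[tab$sex == "F" & tab$zygosity_class == "MZ", ]
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(pm$n_ever / pm$n_total - 0.3), 3 * se)
  expect_lt(abs(pf$n_ever / pf$n_total - 0.45),
            3 * sqrt(0.45 * 0.55 / n))
})
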