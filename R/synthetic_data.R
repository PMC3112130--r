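# Synthetic twin-cohort generator. Draws bivariate-normal liabilities at
# each group's implied correlation, dichotomizes at sex/zygosity/cohort
# thresholds, and emits a twin_dataset with the same structure as the
# registry extracts the analysis is designed for. One RNG stream per group
# x cohort (derived deterministically from the master seed) keeps every
# group's draws stable when other groups' counts change.

#' Simulation configuration
#'
#' @param cohorts Character vector of cohort labels.
#' @param counts Data frame with columns \code{cohort}, \code{group},
#'   \code{n_pairs}, \code{n_singletons}.
#' @param prevalence Data frame with columns \code{cohort}, \code{sex}
#'   (M/F), \code{zygosity} (MZ/DZ), \code{prev} in (0,1); converted to
#'   thresholds.
#' @param A,C,E Generating variance shares: scalars or 2 x K matrices
#'   (rows M/F, columns cohorts); each cell triple must sum to 1.
#' @param rcdos Shared-environment correlation in DOS pairs, per cohort
#'   (scalar recycled).
#' @param dos_male_frac Fraction of DOS singletons that are male
#'   (default 0.5).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(cohorts, counts, prevalence, A, C, E, rcdos = 1,
                       dos_male_frac = 0.5) {
  K <- length(cohorts)
  stopifnot(K >= 1, all(c("cohort", "group", "n_pairs", "n_singletons")
                        %in% names(counts)),
            all(c("cohort", "sex", "zygosity", "prev") %in% names(prevalence)))
  if (any(counts$n_pairs < 0) || any(counts$n_singletons < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(prevalence$prev <= 0) || any(prevalence$prev >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!all(counts$cohort %in% cohorts)) {
    stop("counts reference unknown cohorts", call. = FALSE)
  }
  Am <- matrix(A, 2, K); Cm <- matrix(C, 2, K); Em <- matrix(E, 2, K)
  if (any(abs(Am + Cm + Em - 1) > 1e-8)) {
    stop("generating A + C + E must equal 1 per sex and cohort",
         call. = FALSE)
  }
  tau <- array(NA_real_, dim = c(2, 2, K),
               dimnames = list(c("M", "F"), c("MZ", "DZ"), cohorts))
  for (i in seq_len(nrow(prevalence))) {
    r <- prevalence[i, ]
    tau[r$sex, r$zygosity, r$cohort] <-
      threshold_from_prevalence(r$prev)
  }
  if (any(is.na(tau[, , unique(counts$cohort), drop = FALSE]))) {
    stop("prevalence must cover every sex x zygosity x cohort cell",
         call. = FALSE)
  }
  structure(list(cohorts = cohorts, counts = counts,
                 params = ace_params(Am, Cm, Em, rep_len(rcdos, K), tau,
                                     cohorts),
                 dos_male_frac = dos_male_frac),
            class = "sim_config")
}

#' The combined two-cohort preset
#'
#' Emulates the study conditions of a two-wave young-adult twin sample:
#' pair and singleton counts per zygosity-sex group matching the described
#' cohorts (totals 2669 and 2339 individuals), per-cell prevalences from
#' the printed prevalence table (same-sex and opposite-sex DZ pooled per
#' sex), and generating variance shares at the combined-cohort estimates
#' A = 0.55, C = 0.23 with E = 0.22 absorbing the one-percent rounding
#' remainder so the liability variance is exactly 1; Rcdos = 1.
#'
#' @return A \code{sim_config}.
#' @export
preset_paper_combined <- function() {
  cohorts <- c("1993-1995", "2009-2010")
  counts <- data.frame(
    cohort = rep(cohorts, each = 5),
    group = rep(c("MZM", "DZM", "MZF", "DZF", "DOS"), 2),
    n_pairs = c(206, 178, 326, 227, 377,
                105, 74, 269, 149, 166),
    n_singletons = c(3, 7, 6, 8, 17,
                     86, 90, 165, 146, 326),
    stringsAsFactors = FALSE)
  prevalence <- data.frame(
    cohort = rep(cohorts, each = 4),
    sex = rep(c("M", "M", "F", "F"), 2),
    zygosity = rep(c("MZ", "DZ"), 4),
    prev = c(190 / 415, (184 + 218) / (363 + 384),
             224 / 658, (195 + 176) / (462 + 385),
             44 / 301, (69 + 62) / (239 + 228),
             128 / 728, (122 + 102) / (445 + 400)),
    stringsAsFactors = FALSE)
  sim_config(cohorts, counts, prevalence,
             A = 0.55, C = 0.23, E = 0.22, rcdos = 1)
}

# deterministic sub-seed per (cohort, group) stream
.stream_seed <- function(seed, k, g) {
  (abs(seed) %% 1000003L) * 1000L + k * 10L + g
}

#' Simulate a twin-pair dataset
#'
#' For every pair the two liabilities are standard bivariate normal at the
#' group's implied correlation (from the generating ACE parameters) and are
#' dichotomized at the sex/zygosity/cohort thresholds; singletons are
#' univariate draws. Fully reproducible: each group x cohort cell has its
#' own RNG stream derived from the master seed.
#'
#' @param config A \code{sim_config}.
#' @param seed Integer master seed.
#' @return A \code{twin_dataset}.
#' @export
simulate_twins <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  recs <- list()
  for (i in seq_len(nrow(config$counts))) {
    row <- config$counts[i, ]
    g <- row$group; cohort <- row$cohort
    k <- match(cohort, config$cohorts)
    gi <- match(g, TWIN_GROUPS)
    set.seed(.stream_seed(seed, k, gi))
    s1 <- if (g %in% c("MZF", "DZF")) "F" else "M"
    s2 <- if (g %in% c("MZM", "DZM")) "M" else "F"
    zg <- if (g %in% c("MZM", "MZF")) "MZ" else "DZ"
    t1 <- p$tau[s1, zg, cohort]
    t2 <- p$tau[s2, zg, cohort]
    rho <- min(max(implied_correlation(p, g, cohort), -1), 1)
    np <- row$n_pairs; nsg <- row$n_singletons
    if (np > 0) {
      z1 <- stats::rnorm(np)
      z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(np)
      recs[[length(recs) + 1]] <- data.frame(
        family_id = sprintf("%d-%s-P%05d", k, g, seq_len(np)),
        group = g, cohort = cohort,
        pheno1 = as.integer(z1 > t1), pheno2 = as.integer(z2 > t2),
        stringsAsFactors = FALSE)
    }
    if (nsg > 0) {
      if (g == "DOS") {
        male <- stats::runif(nsg) < config$dos_male_frac
      } else {
        male <- rep(TRUE, nsg)  # same-sex: role 1 by convention
      }
      tt <- ifelse(male, t1, t2)
      y <- as.integer(stats::rnorm(nsg) > tt)
      recs[[length(recs) + 1]] <- data.frame(
        family_id = sprintf("%d-%s-S%05d", k, g, seq_len(nsg)),
        group = g, cohort = cohort,
        pheno1 = ifelse(male, y, NA_integer_),
        pheno2 = ifelse(male, NA_integer_, y),
        stringsAsFactors = FALSE)
    }
  }
  ds <- twin_dataset(do.call(rbind, recs))
  attr(ds, "cohorts") <- config$cohorts
  ds
}

#' Apply a ladder model's structure to a configuration and simulate
#'
#' Transforms the generating parameters to satisfy the given model id
#' before simulating: Rcdos is set to 1 for models 2 and beyond; shares are
#' averaged (then renormalized) over cohorts for models 3-5 (men, women,
#' both) and additionally over sexes for model 6; models 7 and 8 zero out A
#' or C respectively, rescaling the remaining shares to unit variance.
#'
#' @param id Model id 1-8.
#' @param config Base \code{sim_config}.
#' @param seed Master seed.
#' @return A \code{twin_dataset}.
#' @export
simulate_under_model <- function(id, config = preset_paper_combined(),
                                 seed = 1) {
  stopifnot(id %in% 1:8, inherits(config, "sim_config"))
  p <- config$params
  A <- p$A; C <- p$C; E <- p$E
  rcdos <- p$rcdos
  eq_cohort <- function(M, sexrow) {
    M[sexrow, ] <- mean(M[sexrow, ]); M
  }
  if (id >= 2) rcdos[] <- 1
  if (id %in% c(3, 5) || id >= 6) {
    A <- eq_cohort(A, 1); C <- eq_cohort(C, 1); E <- eq_cohort(E, 1)
  }
  if (id %in% c(4, 5) || id >= 6) {
    A <- eq_cohort(A, 2); C <- eq_cohort(C, 2); E <- eq_cohort(E, 2)
  }
  if (id >= 6) {
    A[] <- mean(A); C[] <- mean(C); E[] <- mean(E)
  }
  if (id == 7) {
    s <- C + E; C <- C / s; E <- E / s; A[] <- 0
  }
  if (id == 8) {
    s <- A + E; A <- A / s; E <- E / s; C[] <- 0
  }
  # renormalize against accumulated rounding
  tot <- A + C + E
  A <- A / tot; C <- C / tot; E <- E / tot
  cfg <- config
  cfg$params <- ace_params(A, C, E, rcdos, p$tau, p$cohorts)
  simulate_twins(cfg, seed = seed)
}
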