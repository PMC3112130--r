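# Tetrachoric twin correlations: per-group maximum-likelihood estimation of
# the latent liability correlation from 2x2 concordance tables, with free
# thresholds and profile-likelihood confidence intervals.

#' Cross-tabulate a group's pairs and singletons
#'
#' Builds the sufficient statistics for tetrachoric estimation: joint counts
#' of complete pairs by phenotype pattern plus marginal counts of singletons
#' by role (twin 1 / twin 2) and outcome. For DOS records the roles are
#' male / female.
#'
#' @param ds A \code{twin_dataset}.
#' @param group One of MZM, DZM, MZF, DZF, DOS.
#' @param cohort A cohort label, or \code{"combined"} to pool all cohorts.
#' @return List of class \code{concordance_table} with counts \code{n11},
#'   \code{n10}, \code{n01}, \code{n00}, \code{s1a}, \code{s1u}, \code{s2a},
#'   \code{s2u}.
#' @export
concordance_table <- function(ds, group, cohort = "combined") {
  stopifnot(inherits(ds, "twin_dataset"))
  sel <- ds$group == group
  if (!identical(cohort, "combined")) sel <- sel & ds$cohort == cohort
  sub <- ds[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no records for group ", group, " in cohort ", cohort, call. = FALSE)
  }
  p1 <- sub$pheno1; p2 <- sub$pheno2
  pair <- !is.na(p1) & !is.na(p2)
  structure(list(
    n11 = sum(pair & p1 == 1 & p2 == 1),
    n10 = sum(pair & p1 == 1 & p2 == 0),
    n01 = sum(pair & p1 == 0 & p2 == 1),
    n00 = sum(pair & p1 == 0 & p2 == 0),
    s1a = sum(!pair & !is.na(p1) & p1 == 1),
    s1u = sum(!pair & !is.na(p1) & p1 == 0),
    s2a = sum(!pair & !is.na(p2) & p2 == 1),
    s2u = sum(!pair & !is.na(p2) & p2 == 0)),
    group = group, cohort = cohort, class = "concordance_table")
}

#' Build a concordance table directly from counts
#'
#' @param n11,n10,n01,n00 Pair counts by joint outcome (affected/affected,
#'   affected/unaffected, ...). Non-negative; non-integer weights allowed.
#' @param s1a,s1u,s2a,s2u Singleton counts (affected/unaffected) by role.
#' @return A \code{concordance_table}.
#' @export
concordance_counts <- function(n11, n10, n01, n00,
                               s1a = 0, s1u = 0, s2a = 0, s2u = 0) {
  cts <- list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
              s1a = s1a, s1u = s1u, s2a = s2a, s2u = s2u)
  if (any(unlist(cts) < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(cts, class = "concordance_table")
}

# deviance (-2 log multinomial/Bernoulli likelihood) of one table
.tetra_dev <- function(r, tau1, tau2, tab) {
  p <- cell_probabilities(tau1, tau2, r)
  lp <- function(x) log(pmax(x, 1e-300))
  m1 <- stats::pnorm(tau1, lower.tail = FALSE)
  m2 <- stats::pnorm(tau2, lower.tail = FALSE)
  -2 * (tab$n11 * lp(p$p11) + tab$n10 * lp(p$p10) +
          tab$n01 * lp(p$p01) + tab$n00 * lp(p$p00) +
          tab$s1a * lp(m1) + tab$s1u * lp(1 - m1) +
          tab$s2a * lp(m2) + tab$s2u * lp(1 - m2))
}

# marginal prevalence estimates of one table, clamped away from 0/1
.tetra_margins <- function(tab) {
  n1 <- tab$n11 + tab$n10 + tab$n01 + tab$n00 + tab$s1a + tab$s1u
  n2 <- tab$n11 + tab$n10 + tab$n01 + tab$n00 + tab$s2a + tab$s2u
  eps1 <- 1 / (2 * max(n1, 1)); eps2 <- 1 / (2 * max(n2, 1))
  p1 <- (tab$n11 + tab$n10 + tab$s1a) / max(n1, 1)
  p2 <- (tab$n11 + tab$n01 + tab$s2a) / max(n2, 1)
  c(min(max(p1, eps1), 1 - eps1), min(max(p2, eps2), 1 - eps2))
}

# Joint ML fit of a common correlation across one or more tables, each with
# its own threshold(s). share_threshold: tau1 = tau2 within each table.
.tetra_fit <- function(tabs, share_threshold = TRUE,
                       r_starts = c(-0.5, 0, 0.5), r_fixed = NULL) {
  ntau <- if (share_threshold) 1L else 2L
  tau0 <- unlist(lapply(tabs, function(tb) {
    m <- .tetra_margins(tb)
    if (share_threshold) {
      stats::qnorm(mean(m), lower.tail = FALSE)
    } else stats::qnorm(m, lower.tail = FALSE)
  }))
  dev_all <- function(r, taus) {
    d <- 0
    for (i in seq_along(tabs)) {
      tt <- taus[((i - 1) * ntau + 1):(i * ntau)]
      d <- d + .tetra_dev(r, tt[1], tt[ntau], tabs[[i]])
    }
    d
  }
  if (!is.null(r_fixed)) {
    obj <- function(par) dev_all(r_fixed, par)
    o <- stats::optim(tau0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    return(list(r = r_fixed, taus = o$par, minus2LL = o$value,
                convergence = o$convergence))
  }
  obj <- function(par) dev_all(tanh(par[1]), par[-1])
  best <- NULL
  for (r0 in r_starts) {
    o <- stats::optim(c(atanh(r0), tau0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  list(r = tanh(best$par[1]), taus = best$par[-1], minus2LL = best$value,
       convergence = best$convergence)
}

#' Maximum-likelihood tetrachoric correlation from a concordance table
#'
#' Estimates the latent liability correlation jointly with the threshold(s)
#' by maximizing the multinomial likelihood with bivariate-normal cell
#' probabilities; singleton counts contribute their Bernoulli margins. The
#' correlation is optimized on the Fisher-z scale by quasi-Newton iterations
#' from three deterministic starts. The 95% confidence interval is
#' profile-likelihood based (deviance increase of 3.84 with thresholds
#' re-optimized), truncated at \eqn{\pm 1}.
#'
#' @param tab A \code{concordance_table}.
#' @param share_threshold Logical; if TRUE (same-sex groups) both twins
#'   share one threshold, if FALSE (DOS) each role has its own.
#' @param ci Logical; compute the profile confidence interval.
#' @param conf Confidence level (default 0.95).
#' @return List of class \code{tetrachoric_fit}: \code{r}, \code{ci_low},
#'   \code{ci_high}, \code{tau1}, \code{tau2}, \code{minus2LL},
#'   \code{boundary} flag.
#' @export
estimate_tetrachoric <- function(tab, share_threshold = TRUE, ci = TRUE,
                                 conf = 0.95) {
  stopifnot(inherits(tab, "concordance_table"))
  npairs <- tab$n11 + tab$n10 + tab$n01 + tab$n00
  total <- npairs + tab$s1a + tab$s1u + tab$s2a + tab$s2u
  if (total <= 0) stop("empty concordance table", call. = FALSE)
  # perfectly concordant (or perfectly discordant) pairs put the MLE of r on
  # the +/-1 boundary; all mass in a single cell is degenerate as well
  boundary <- npairs > 0 &&
    ((tab$n10 + tab$n01 == 0) || (tab$n11 + tab$n00 == 0))
  fit <- .tetra_fit(list(tab), share_threshold = share_threshold)
  r <- fit$r
  if (abs(r) > 0.9999) { r <- sign(r); boundary <- TRUE }
  tau1 <- fit$taus[1]
  tau2 <- if (share_threshold) fit$taus[1] else fit$taus[2]
  res <- list(r = r, ci_low = NA_real_, ci_high = NA_real_,
              tau1 = tau1, tau2 = tau2, minus2LL = fit$minus2LL,
              boundary = boundary)
  if (ci) {
    crit <- fit$minus2LL + stats::qchisq(conf, df = 1)
    pdev <- function(rv) {
      .tetra_fit(list(tab), share_threshold = share_threshold,
                 r_fixed = rv)$minus2LL
    }
    res$ci_low <- .profile_root(pdev, r, crit, lower = TRUE,
                                lim = -1, tol = 1e-4)
    res$ci_high <- .profile_root(pdev, r, crit, lower = FALSE,
                                 lim = 1, tol = 1e-4)
  }
  class(res) <- "tetrachoric_fit"
  res
}

# Find the parameter value where the profile deviance crosses `crit`,
# between the MLE `hat` and the boundary `lim`. Scans outward from the MLE
# (so warm-start chains in `pdev` stay effective), then refines by uniroot;
# returns the boundary when the deviance never reaches crit (truncation).
.profile_root <- function(pdev, hat, crit, lower, lim, tol = 1e-4,
                          nsteps = 8) {
  bound <- if (lower) max(lim + 1e-6, -0.99999) else min(lim - 1e-6, 0.99999)
  if (abs(hat - bound) < tol) return(lim)
  f <- function(v) pdev(v) - crit
  prev <- hat
  for (v in hat + (bound - hat) * seq_len(nsteps) / nsteps) {
    if (f(v) > 0) {
      # plain bisection: tolerant of the slight non-determinism that
      # warm-started constrained refits introduce near the crossing
      a <- prev
      b <- v
      for (i in 1:60) {
        if (abs(b - a) < tol) break
        m <- (a + b) / 2
        if (f(m) > 0) b <- m else a <- m
      }
      return((a + b) / 2)
    }
    prev <- v
  }
  lim
}

#' Tetrachoric correlations for every zygosity-sex group and cohort
#'
#' The per-group correlation table: one row per group (MZM, DZM, MZF, DZF,
#' DOS) with columns for each cohort and for the combined data. Same-sex
#' groups share one threshold per twin pair; DOS estimates separate male and
#' female thresholds. When pooling cohorts the thresholds stay
#' cohort-specific (a single correlation is fitted jointly across the
#' per-cohort tables) unless \code{pool_thresholds = TRUE}, which collapses
#' the cohorts into a single table first.
#'
#' @param ds A \code{twin_dataset} (all five groups present).
#' @param ci Logical; compute profile confidence intervals.
#' @param pool_thresholds Logical; see Description.
#' @return Data frame with columns \code{group}, \code{cohort} (cohort
#'   labels plus \code{"combined"}), \code{r}, \code{ci_low},
#'   \code{ci_high}, \code{minus2LL}.
#' @export
correlation_table <- function(ds, ci = TRUE, pool_thresholds = FALSE) {
  stopifnot(inherits(ds, "twin_dataset"))
  cohorts <- attr(ds, "cohorts")
  rows <- list()
  for (g in TWIN_GROUPS) {
    share <- g != "DOS"
    for (k in cohorts) {
      fit <- estimate_tetrachoric(concordance_table(ds, g, k),
                                  share_threshold = share, ci = ci)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, cohort = k, r = fit$r, ci_low = fit$ci_low,
        ci_high = fit$ci_high, minus2LL = fit$minus2LL)
    }
    if (length(cohorts) > 1) {
      if (pool_thresholds) {
        fit <- estimate_tetrachoric(concordance_table(ds, g, "combined"),
                                    share_threshold = share, ci = ci)
        comb <- list(r = fit$r, ci_low = fit$ci_low, ci_high = fit$ci_high,
                     minus2LL = fit$minus2LL)
      } else {
        tabs <- lapply(cohorts, function(k) concordance_table(ds, g, k))
        jf <- .tetra_fit(tabs, share_threshold = share)
        comb <- list(r = jf$r, ci_low = NA_real_, ci_high = NA_real_,
                     minus2LL = jf$minus2LL)
        if (ci) {
          crit <- jf$minus2LL + stats::qchisq(0.95, df = 1)
          pdev <- function(rv) {
            .tetra_fit(tabs, share_threshold = share, r_fixed = rv)$minus2LL
          }
          comb$ci_low <- .profile_root(pdev, jf$r, crit, TRUE, -1)
          comb$ci_high <- .profile_root(pdev, jf$r, crit, FALSE, 1)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = g, cohort = "combined", r = comb$r, ci_low = comb$ci_low,
        ci_high = comb$ci_high, minus2LL = comb$minus2LL)
    } else {
      last <- rows[[length(rows)]]
      last$cohort <- "combined"
      rows[[length(rows) + 1]] <- last
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a correlation table in the printed two-decimal layout
#'
#' @param tab Output of \code{\link{correlation_table}}.
#' @return Data frame with \code{r} and \code{"low - high"} CI strings.
#' @export
format_correlation_table <- function(tab) {
  data.frame(group = tab$group, cohort = tab$cohort,
             r = sprintf("%.2f", tab$r),
             ci = ifelse(is.na(tab$ci_low), "",
                         sprintf("%.2f - %.2f", tab$ci_low, tab$ci_high)))
}
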