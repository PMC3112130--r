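# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the BVN oracle is 1-D adaptive quadrature of the
# conditional-normal reduction, the chi-square tail oracle is a direct
# series/continued-fraction evaluation of the regularized incomplete gamma,
# and the tetrachoric oracle is a brute-force profile grid search.

# P(X > t1, Y > t2) by adaptive quadrature over the conditional CDF
bvn_oracle <- function(t1, t2, r) {
  f <- function(x) {
    stats::dnorm(x) *
      stats::pnorm((t2 - r * x) / sqrt(1 - r^2), lower.tail = FALSE)
  }
  stats::integrate(f, t1, Inf, rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# upper regularized incomplete gamma Q(a, x): series for P when x < a + 1,
# modified Lentz continued fraction for Q otherwise
gammq_oracle <- function(a, x) {
  if (x <= 0) return(1)
  if (x < a + 1) {
    ap <- a
    s <- 1 / a
    del <- s
    for (i in 1:1000) {
      ap <- ap + 1
      del <- del * x / ap
      s <- s + del
      if (abs(del) < abs(s) * 1e-16) break
    }
    1 - s * exp(-x + a * log(x) - lgamma(a))
  } else {
    b <- x + 1 - a
    cc <- 1e300
    d <- 1 / b
    h <- d
    for (i in 1:1000) {
      an <- -i * (i - a)
      b <- b + 2
      d <- an * d + b
      if (abs(d) < 1e-300) d <- 1e-300
      cc <- b + an / cc
      if (abs(cc) < 1e-300) cc <- 1e-300
      d <- 1 / d
      del <- d * cc
      h <- h * del
      if (abs(del - 1) < 1e-16) break
    }
    exp(-x + a * log(x) - lgamma(a)) * h
  }
}

chisq_upper_oracle <- function(chi2, df) gammq_oracle(df / 2, chi2 / 2)

# Brute-force tetrachoric oracle: deviance minimized over a fine grid of r
# with the threshold profiled out at each grid point (warm-started along
# the grid). Returns the grid argmin and its deviance.
grid_tetrachoric_oracle <- function(tab, step = 1e-3) {
  rs <- seq(-0.999, 0.999, by = step)
  m <- twinliab:::.tetra_margins(tab)
  tau <- stats::qnorm(mean(m), lower.tail = FALSE)
  best_r <- NA_real_
  best_dev <- Inf
  for (r in rs) {
    o <- stats::optimize(function(t) twinliab:::.tetra_dev(r, t, t, tab),
                         interval = c(tau - 1, tau + 1), tol = 1e-7)
    tau <- o$minimum  # warm interval center for the next grid point
    if (o$objective < best_dev) {
      best_dev <- o$objective
      best_r <- r
    }
  }
  list(r = best_r, dev = best_dev)
}

# A dataset realizing the printed prevalence counts exactly, one singleton
# per individual (prevalence arithmetic does not depend on pairing).
table1_dataset <- function() {
  cells <- rbind(
    data.frame(cohort = "1993-1995", sex = "M",
               class = c("MZ", "DZss", "DZos"),
               n = c(415, 363, 384), ever = c(190, 184, 218)),
    data.frame(cohort = "1993-1995", sex = "F",
               class = c("MZ", "DZss", "DZos"),
               n = c(658, 462, 385), ever = c(224, 195, 176)),
    data.frame(cohort = "2009-2010", sex = "M",
               class = c("MZ", "DZss", "DZos"),
               n = c(301, 239, 228), ever = c(44, 69, 62)),
    data.frame(cohort = "2009-2010", sex = "F",
               class = c("MZ", "DZss", "DZos"),
               n = c(728, 445, 400), ever = c(128, 122, 102)))
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    grp <- if (cl$class == "MZ") {
      if (cl$sex == "M") "MZM" else "MZF"
    } else if (cl$class == "DZss") {
      if (cl$sex == "M") "DZM" else "DZF"
    } else "DOS"
    y <- c(rep(1L, cl$ever), rep(0L, cl$n - cl$ever))
    male_slot <- grp != "DOS" || cl$sex == "M"
    data.frame(
      family_id = sprintf("%s-%s-%s-%04d", cl$cohort, grp, cl$sex,
                          seq_len(cl$n)),
      group = grp, cohort = cl$cohort,
      pheno1 = if (male_slot) y else NA_integer_,
      pheno2 = if (male_slot) NA_integer_ else y,
      stringsAsFactors = FALSE)
  }))
  twin_dataset(recs)
}

# small two-cohort config for pipeline tests: preset structure at a
# fraction of the sample size
scaled_preset <- function(frac = 0.5) {
  cfg <- preset_paper_combined()
  cfg$counts$n_pairs <- ceiling(cfg$counts$n_pairs * frac)
  cfg$counts$n_singletons <- ceiling(cfg$counts$n_singletons * frac)
  cfg
}

# multinomial concordance draw at given (r, tau) - independent of the
# package's liability simulator
draw_table <- function(n_pairs, r, tau1, tau2 = tau1) {
  p <- cell_probabilities(tau1, tau2, r)
  cnt <- stats::rmultinom(1, n_pairs, c(p$p11, p$p10, p$p01, p$p00))
  concordance_counts(cnt[1], cnt[2], cnt[3], cnt[4])
}
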