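# Nested-model likelihood-ratio ladder: eight ACE specifications compared
# by chi-square deviance differences, with the alpha = 0.01 decision rule.

#' Upper-tail chi-square p-value
#'
#' @param chi2 Non-negative likelihood-ratio statistic.
#' @param df Positive integer degrees of freedom.
#' @return \eqn{P(\chi^2_{df} \ge chi2)}.
#' @export
chi2_pvalue <- function(chi2, df) {
  if (any(chi2 < 0) || any(df < 1) || any(df != round(df))) {
    stop("chi2 must be >= 0 and df a positive integer", call. = FALSE)
  }
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio comparison of two nested fits
#'
#' Twice the log-likelihood difference between a sub-model and its parent is
#' referred to a chi-square with the difference in df. Accepts full
#' \code{ace_fit} objects or bare lists with \code{minus2LL} and \code{df}
#' (e.g. printed table values). Tiny negative statistics from optimizer
#' tolerance are clamped to zero and flagged.
#'
#' @param sub,parent Fits (sub nested in parent: fewer free parameters,
#'   larger df).
#' @return List of class \code{ladder_row}: \code{minus2LL}, \code{df},
#'   \code{chi2}, \code{delta_df}, \code{p}, \code{clamped}.
#' @export
lrt <- function(sub, parent) {
  if (inherits(sub, "ace_fit") && inherits(parent, "ace_fit")) {
    ok <- .is_nested(sub$spec$id, parent$spec$id)
    if (!ok) {
      stop("model ", sub$spec$id, " is not nested in model ",
           parent$spec$id, call. = FALSE)
    }
  }
  delta_df <- sub$df - parent$df
  if (delta_df <= 0) stop("sub-model must have larger df than its parent",
                          call. = FALSE)
  chi2 <- sub$minus2LL - parent$minus2LL
  clamped <- FALSE
  if (chi2 < 0) {
    if (chi2 < -1e-6) {
      warning("negative LRT statistic (", format(chi2),
              "); clamped to 0 - check convergence", call. = FALSE)
    }
    chi2 <- 0
    clamped <- TRUE
  }
  structure(list(minus2LL = sub$minus2LL, df = sub$df, chi2 = chi2,
                 delta_df = delta_df, p = chi2_pvalue(chi2, delta_df),
                 clamped = clamped),
            class = "ladder_row")
}

# comparison topology of the ladder: parent chain lookups
.ladder_parents <- c(NA, 1, 2, 2, 2, 5, 6, 6)

.is_nested <- function(sub_id, parent_id) {
  id <- sub_id
  while (!is.na(id)) {
    if (!is.na(.ladder_parents[id]) && .ladder_parents[id] == parent_id) {
      return(TRUE)
    }
    id <- .ladder_parents[id]
  }
  FALSE
}

#' Format a p-value at four decimals
#'
#' Values below the printable resolution are reported as \code{"< 0.0001"}.
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.00005, "< 0.0001", sprintf("%.4f", p))
}

#' Run the full eight-model ladder on a dataset
#'
#' Fits models 1-8 in order (each warm-started from its parent's
#' estimates), computes the likelihood-ratio comparisons along the ladder
#' topology (2 vs 1; 3, 4, 5 vs 2; 6 vs 5; 7, 8 vs 6), and applies the
#' decision rule: walk the chain 1 -> 2 -> 5 -> 6 -> (7 or 8), accepting
#' each simplification whose p-value is at least \code{alpha}.
#'
#' @param ds A \code{twin_dataset} with both cohorts and all five groups.
#' @param alpha Decision threshold (default 0.01).
#' @param n_starts Multi-start schedule length passed to
#'   \code{\link{fit_ace}}.
#' @return Object of class \code{ladder_report}: \code{rows} (data frame
#'   mirroring the printed comparison-table columns), \code{fits} (list of
#'   \code{ace_fit}), \code{accepted} (model id), \code{alpha},
#'   \code{notes}.
#' @export
run_ladder <- function(ds, alpha = 0.01, n_starts = 3) {
  stopifnot(inherits(ds, "twin_dataset"))
  fits <- vector("list", 8)
  rows <- vector("list", 8)
  for (id in 1:8) {
    spec <- ace_model_spec(id, n_cohorts = length(attr(ds, "cohorts")))
    parent_id <- .ladder_parents[id]
    warm <- if (!is.na(parent_id)) fits[[parent_id]]$params else NULL
    fits[[id]] <- fit_ace(ds, spec, start = warm, n_starts = n_starts)
    if (is.na(parent_id)) {
      rows[[id]] <- data.frame(
        model = id, description = spec$description,
        minus2LL = fits[[id]]$minus2LL, df = fits[[id]]$df,
        versus = NA_integer_, chi2 = NA_real_, delta_df = NA_integer_,
        p = NA_real_)
    } else {
      lr <- lrt(fits[[id]], fits[[parent_id]])
      rows[[id]] <- data.frame(
        model = id, description = spec$description,
        minus2LL = fits[[id]]$minus2LL, df = fits[[id]]$df,
        versus = parent_id, chi2 = lr$chi2, delta_df = lr$delta_df,
        p = lr$p)
    }
  }
  rows <- do.call(rbind, rows)
  p_of <- function(id) rows$p[rows$model == id]
  accepted <- 1L
  if (p_of(2) >= alpha) accepted <- 2L
  if (accepted == 2L && p_of(5) >= alpha) accepted <- 5L
  if (accepted == 5L && p_of(6) >= alpha) accepted <- 6L
  if (accepted == 6L) {
    ok7 <- p_of(7) >= alpha
    ok8 <- p_of(8) >= alpha
    if (ok7 && ok8) {
      accepted <- if (rows$minus2LL[7] <= rows$minus2LL[8]) 7L else 8L
    } else if (ok7) accepted <- 7L else if (ok8) accepted <- 8L
  }
  notes <- c(
    sex_difference_p = p_of(6),
    cohort_equality_p = p_of(5),
    rcdos_p = p_of(2))
  structure(list(rows = rows, fits = fits, accepted = accepted,
                 alpha = alpha, notes = notes),
            class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  r <- x$rows
  cat(sprintf("%2s %-42s %9s %5s %3s %8s %4s %s\n",
              "#", "model", "-2LL", "df", "vs", "chi2", "ddf", "p"))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("%2d %-42s %9.3f %5d %3s %8s %4s %s\n",
                r$model[i], r$description[i], r$minus2LL[i], r$df[i],
                ifelse(is.na(r$versus[i]), "", r$versus[i]),
                ifelse(is.na(r$chi2[i]), "", sprintf("%.3f", r$chi2[i])),
                ifelse(is.na(r$delta_df[i]), "", r$delta_df[i]),
                ifelse(is.na(r$p[i]), "", format_pvalue(r$p[i]))))
  }
  cat("Accepted model:", x$accepted, "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' One-paragraph text summary of a ladder report
#'
#' States the accepted model, whether the cohort-equality (gene-environment
#' interaction) simplification held, and whether sex differences were
#' detected, relative to the report's alpha.
#'
#' @param report A \code{ladder_report}.
#' @return Character vector of lines.
#' @export
summarize_ladder <- function(report) {
  a <- report$alpha
  n <- report$notes
  acc <- report$fits[[report$accepted]]
  lines <- c(
    sprintf("Accepted model: %d (%s), -2LL = %.3f, df = %d.",
            report$accepted, acc$spec$description, acc$minus2LL, acc$df),
    sprintf(
      "Cohort equality of A/C/E %s rejected (p = %s vs alpha = %.2f): %s.",
      if (n[["cohort_equality_p"]] < a) "was" else "was not",
      format_pvalue(n[["cohort_equality_p"]]), a,
      if (n[["cohort_equality_p"]] < a) {
        "evidence for cohort-moderated (GxE) genetic architecture"
      } else "no evidence for gene-environment interaction across cohorts"),
    sprintf("Qualitative sex differences (Rcdos = 1) %s rejected (p = %s).",
            if (n[["rcdos_p"]] < a) "were" else "were not",
            format_pvalue(n[["rcdos_p"]])),
    sprintf("Quantitative sex differences %s rejected (p = %s).",
            if (n[["sex_difference_p"]] < a) "were" else "were not",
            format_pvalue(n[["sex_difference_p"]])))
  unname(lines)
}
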