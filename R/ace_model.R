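# Five-group ACE liability model with qualitative sex limitation (free
# shared-environment correlation in opposite-sex pairs) and birth-cohort
# structure, fitted by full-information maximum likelihood on raw pair data.
#
# Parameterization: standardized variance shares A, C, E per sex x cohort
# equality class with A + C + E = 1 (unit liability variance). Internally
# the shares are optimized on a stick-breaking logit scale, which keeps the
# optimizer inside the admissible simplex; the reported degrees of freedom
# nonetheless follow the free-a,c,e-plus-unit-variance-constraint
# convention (one nonlinear constraint per sex x cohort cell), the
# accounting used in the classical five-group treatment of this design.

#' ACE parameter set
#'
#' @param A,C,E 2 x K matrices of variance shares (rows \code{M}, \code{F};
#'   one column per cohort), each row-cell triple summing to 1.
#' @param rcdos Length-K vector: correlation between the male and female
#'   shared-environment factors in opposite-sex DZ pairs, per cohort.
#' @param tau 2 x 2 x K array of liability thresholds, dimensions sex
#'   (\code{M}, \code{F}) by zygosity (\code{MZ}, \code{DZ}) by cohort.
#' @param cohorts Character vector of cohort labels (length K).
#' @return Object of class \code{ace_params}.
#' @export
ace_params <- function(A, C, E, rcdos, tau, cohorts) {
  K <- length(cohorts)
  A <- matrix(A, 2, K, dimnames = list(c("M", "F"), cohorts))
  C <- matrix(C, 2, K, dimnames = list(c("M", "F"), cohorts))
  E <- matrix(E, 2, K, dimnames = list(c("M", "F"), cohorts))
  if (any(abs(A + C + E - 1) > 1e-8)) {
    stop("A + C + E must equal 1 for every sex x cohort cell", call. = FALSE)
  }
  if (any(A < -1e-12 | C < -1e-12 | E < -1e-12)) {
    stop("variance shares must be non-negative", call. = FALSE)
  }
  tau <- array(tau, dim = c(2, 2, K),
               dimnames = list(c("M", "F"), c("MZ", "DZ"), cohorts))
  rcdos <- stats::setNames(rep_len(rcdos, K), cohorts)
  structure(list(A = A, C = C, E = E, rcdos = rcdos, tau = tau,
                 cohorts = cohorts),
            class = "ace_params")
}

#' Twin correlation implied by ACE parameters
#'
#' MZ same-sex pairs correlate \eqn{A + C}; DZ same-sex pairs \eqn{A/2 + C}
#' (DZ twins share half their segregating genes, all of the common
#' environment); DOS pairs \eqn{\frac{1}{2} a_M a_F + R_{c,dos}\, c_M c_F}
#' with \eqn{a = \sqrt{A}}, \eqn{c = \sqrt{C}}, cohort-specific parameters.
#'
#' @param params An \code{ace_params}.
#' @param group Zygosity-sex group label.
#' @param cohort Cohort label.
#' @return Implied liability correlation.
#' @export
implied_correlation <- function(params, group, cohort) {
  stopifnot(inherits(params, "ace_params"))
  k <- cohort
  switch(group,
    MZM = params$A["M", k] + params$C["M", k],
    MZF = params$A["F", k] + params$C["F", k],
    DZM = 0.5 * params$A["M", k] + params$C["M", k],
    DZF = 0.5 * params$A["F", k] + params$C["F", k],
    DOS = 0.5 * sqrt(params$A["M", k] * params$A["F", k]) +
      params$rcdos[[k]] * sqrt(params$C["M", k] * params$C["F", k]),
    stop("unknown group ", group, call. = FALSE))
}

#' Log-likelihood contribution of a single pair record
#'
#' Complete pairs contribute the log of the matching joint cell probability
#' at the group's implied correlation; singletons contribute the Bernoulli
#' margin at their own threshold. Zero-probability cells return the clamped
#' value \code{log(1e-300)} with attribute \code{"zero_cell"}.
#'
#' @param rec One-row data frame (or list) with \code{group}, \code{cohort},
#'   \code{pheno1}, \code{pheno2}.
#' @param params An \code{ace_params} with thresholds.
#' @return Log-likelihood contribution (scalar).
#' @export
pair_loglik <- function(rec, params) {
  g <- rec$group; k <- rec$cohort
  s1 <- if (g %in% c("MZF", "DZF")) "F" else "M"
  s2 <- if (g %in% c("MZM", "DZM")) "M" else "F"
  zg <- if (g %in% c("MZM", "MZF")) "MZ" else "DZ"
  t1 <- params$tau[s1, zg, k]
  t2 <- params$tau[s2, zg, k]
  y1 <- rec$pheno1; y2 <- rec$pheno2
  lp <- function(x) {
    if (x < 1e-300) structure(log(1e-300), zero_cell = TRUE) else log(x)
  }
  if (is.na(y1)) return(lp(stats::pnorm(t2, lower.tail = (y2 == 0))))
  if (is.na(y2)) return(lp(stats::pnorm(t1, lower.tail = (y1 == 0))))
  rho <- implied_correlation(params, g, k)
  p <- cell_probabilities(t1, t2, rho)
  cell <- paste0("p", y1, y2)
  lp(p[[cell]])
}

# ---- model specifications (the Table-4 ladder) ------------------------------

#' Specification of one model in the nested ACE ladder
#'
#' Models 1-8: (1) full ACE, sex- and cohort-specific shares with free
#' Rcdos; (2) Rcdos fixed at 1; (3)/(4) shares equated over cohorts for
#' men/women; (5) for both sexes; (6) no sex differences; (7) A dropped;
#' (8) C dropped. Thresholds stay free per sex x zygosity x cohort in every
#' model. Parameter counts use the free-a,c,e convention with one
#' unit-variance constraint per sex x cohort.
#'
#' @param id Model id, 1 through 8.
#' @param n_cohorts Number of cohorts (default 2).
#' @return Object of class \code{ace_model_spec} with the equality-class
#'   map, Rcdos treatment, dropped component, parent model id, and the
#'   parameter/constraint counts.
#' @export
ace_model_spec <- function(id, n_cohorts = 2) {
  K <- n_cohorts
  stopifnot(id %in% 1:8)
  per_sex_cohort <- outer(c("M", "F"), seq_len(K), paste0)
  per_sex <- matrix(rep(c("M", "F"), K), 2, K)
  one <- matrix("T", 2, K)
  def <- switch(id,
    `1` = list(map = per_sex_cohort, rcdos = "free", drop = NA,
               desc = "Full ACE", parent = NA_integer_),
    `2` = list(map = per_sex_cohort, rcdos = "one", drop = NA,
               desc = "Constrain Rcdos at 1", parent = 1L),
    `3` = list(map = rbind(rep("M", K), per_sex_cohort[2, ]), rcdos = "one",
               drop = NA, desc = "EQ ACE for men over cohorts", parent = 2L),
    `4` = list(map = rbind(per_sex_cohort[1, ], rep("F", K)), rcdos = "one",
               drop = NA, desc = "EQ ACE for women over cohorts", parent = 2L),
    `5` = list(map = per_sex, rcdos = "one", drop = NA,
               desc = "EQ ACE for both sexes over cohorts", parent = 2L),
    `6` = list(map = one, rcdos = "one", drop = NA,
               desc = "No sex differences in contributions of A,C,E",
               parent = 5L),
    `7` = list(map = one, rcdos = "one", drop = "A",
               desc = "Drop A", parent = 6L),
    `8` = list(map = one, rcdos = "one", drop = "C",
               desc = "Drop C", parent = 6L))
  classes <- unique(as.vector(def$map))
  paths_per_class <- if (is.na(def$drop)) 3L else 2L
  n_free <- length(classes) * paths_per_class +
    (def$rcdos == "free") * K + 4L * K
  structure(list(id = id, description = def$desc, class_map = def$map,
                 classes = classes, rcdos = def$rcdos, drop = def$drop,
                 parent = def$parent, n_cohorts = K,
                 n_free_params = n_free, n_constraint_equations = 2L * K),
            class = "ace_model_spec")
}

#' Degrees of freedom of a model specification
#'
#' \code{df = n_individuals - n_free_params + n_constraint_equations}. The
#' constraint count is one unit-liability-variance equation per sex x cohort
#' cell (4 for two cohorts) regardless of equality classes.
#'
#' @param spec An \code{ace_model_spec}, or any list with
#'   \code{n_free_params} and \code{n_constraint_equations}.
#' @param n_individuals Number of phenotyped individuals.
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec, n_individuals) {
  n_individuals - spec$n_free_params + spec$n_constraint_equations
}

# ---- sufficient statistics and the FIML objective ---------------------------

# Per (cohort, group) concordance counts plus threshold bookkeeping.
.ace_suffstats <- function(ds) {
  cohorts <- attr(ds, "cohorts")
  rows <- list()
  for (k in seq_along(cohorts)) {
    for (g in TWIN_GROUPS) {
      sel <- ds$group == g & ds$cohort == cohorts[k]
      if (!any(sel)) next
      p1 <- ds$pheno1[sel]; p2 <- ds$pheno2[sel]
      pair <- !is.na(p1) & !is.na(p2)
      s1 <- if (g %in% c("MZF", "DZF")) 2L else 1L  # 1 = M, 2 = F
      s2 <- if (g %in% c("MZM", "DZM")) 1L else 2L
      zg <- if (g %in% c("MZM", "MZF")) 1L else 2L  # 1 = MZ, 2 = DZ
      rows[[length(rows) + 1]] <- data.frame(
        cohort = cohorts[k], k = k, group = g,
        n11 = sum(pair & p1 == 1 & p2 == 1),
        n10 = sum(pair & p1 == 1 & p2 == 0),
        n01 = sum(pair & p1 == 0 & p2 == 1),
        n00 = sum(pair & p1 == 0 & p2 == 0),
        s1a = sum(!pair & !is.na(p1) & p1 == 1),
        s1u = sum(!pair & !is.na(p1) & p1 == 0),
        s2a = sum(!pair & !is.na(p2) & p2 == 1),
        s2u = sum(!pair & !is.na(p2) & p2 == 0),
        # flattened index into tau[sex, zyg, cohort]
        i1 = s1 + 2L * (zg - 1L) + 4L * (k - 1L),
        i2 = s2 + 2L * (zg - 1L) + 4L * (k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Threshold starting values from per-cell sample prevalences.
.tau_start <- function(ss, K) {
  aff <- tot <- numeric(4 * K)
  add <- function(idx, a, n) {
    aff[idx] <<- aff[idx] + a
    tot[idx] <<- tot[idx] + n
  }
  for (i in seq_len(nrow(ss))) {
    r <- ss[i, ]
    n_pairs <- r$n11 + r$n10 + r$n01 + r$n00
    add(r$i1, r$n11 + r$n10 + r$s1a, n_pairs + r$s1a + r$s1u)
    add(r$i2, r$n11 + r$n01 + r$s2a, n_pairs + r$s2a + r$s2u)
  }
  prev <- ifelse(tot > 0, pmin(pmax(aff / pmax(tot, 1), 0.01), 0.99), 0.5)
  stats::qnorm(prev, lower.tail = FALSE)
}

# Per-class share builders on the stick-breaking logit scale. `fix` is NULL
# or list(comp =, value =). Returns list(npar, build(parblock) -> c(A, C)).
.class_builder <- function(drop, fix = NULL) {
  if (is.null(fix)) {
    if (is.na(drop)) {
      return(list(npar = 2L, build = function(p) {
        a <- stats::plogis(p[1]); c(a, (1 - a) * stats::plogis(p[2]))
      }))
    }
    if (drop == "A") {
      return(list(npar = 1L,
                  build = function(p) c(0, stats::plogis(p[1]))))
    }
    return(list(npar = 1L, build = function(p) c(stats::plogis(p[1]), 0)))
  }
  v <- fix$value
  if (is.na(drop)) {
    switch(fix$comp,
      A = list(npar = 1L,
               build = function(p) c(v, (1 - v) * stats::plogis(p[1]))),
      C = list(npar = 1L,
               build = function(p) c((1 - v) * stats::plogis(p[1]), v)),
      E = list(npar = 1L, build = function(p) {
        a <- (1 - v) * stats::plogis(p[1]); c(a, 1 - v - a)
      }),
      stop("unknown component"))
  } else if (drop == "A") {
    switch(fix$comp,
      C = list(npar = 0L, build = function(p) c(0, v)),
      E = list(npar = 0L, build = function(p) c(0, 1 - v)),
      stop("component A is fixed at 0 in this model"))
  } else {
    switch(fix$comp,
      A = list(npar = 0L, build = function(p) c(v, 0)),
      E = list(npar = 0L, build = function(p) c(1 - v, 0)),
      stop("component C is fixed at 0 in this model"))
  }
}

.qlogis_safe <- function(p) stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

# Build pack/unpack machinery for a spec (optionally with one class's
# component fixed). Returns objective(theta), unpack(theta) -> params
# pieces, and start(theta0 shares list) helpers.
.ace_machine <- function(ss, spec, fix_class = NULL, fix = NULL,
                         rcdos_fix = NULL) {
  K <- spec$n_cohorts
  classes <- spec$classes
  builders <- lapply(classes, function(cl) {
    if (!is.null(fix_class) && cl == fix_class) {
      .class_builder(spec$drop, fix)
    } else .class_builder(spec$drop)
  })
  npar_cls <- vapply(builders, `[[`, integer(1), "npar")
  # rcdos entries: free when the spec says so and not pinned by rcdos_fix
  # (a length-K vector with NA marking still-free cohorts)
  rc_base <- if (spec$rcdos == "free") rep(NA_real_, K) else rep(1, K)
  if (!is.null(rcdos_fix)) {
    pin <- !is.na(rcdos_fix)
    rc_base[pin] <- rcdos_fix[pin]
  }
  rc_mask <- is.na(rc_base)
  n_rc <- sum(rc_mask)
  off_cls <- cumsum(c(0L, npar_cls))[seq_along(classes)]
  off_rc <- sum(npar_cls)
  off_tau <- off_rc + n_rc
  ntheta <- off_tau + 4L * K
  cm <- spec$class_map  # 2 x K labels
  cls_idx <- matrix(match(cm, classes), 2, K)
  # Free Rcdos cohorts are optimized on atanh(rho_DOS): the likelihood
  # depends on Rcdos only through the implied DOS correlation, and the
  # direct scale avoids the ridge rcdos * c_M c_F when C approaches 0.
  # Rcdos itself is derived from the fitted rho_DOS afterwards.
  unpack <- function(theta) {
    AC <- vapply(seq_along(classes), function(j) {
      builders[[j]]$build(theta[off_cls[j] + seq_len(npar_cls[j])])
    }, numeric(2))
    A <- matrix(AC[1, cls_idx], 2, K)
    C <- matrix(AC[2, cls_idx], 2, K)
    rho_dos <- rep(NA_real_, K)
    if (n_rc) rho_dos[rc_mask] <- tanh(theta[off_rc + seq_len(n_rc)])
    list(A = A, C = C, rcdos = rc_base, rho_dos = rho_dos,
         tau_flat = theta[off_tau + seq_len(4L * K)])
  }
  # cached per-row vectors: the objective is evaluated thousands of times
  nr <- nrow(ss)
  v_i1 <- ss$i1; v_i2 <- ss$i2; v_k <- ss$k
  m_mzss <- ss$group %in% c("MZM", "MZF")
  m_dzss <- ss$group %in% c("DZM", "DZF")
  m_dos <- ss$group == "DOS"
  v_sex <- ifelse(ss$group %in% c("MZF", "DZF"), 2L, 1L)
  i_own <- (v_k - 1L) * 2L + v_sex  # column-major index into 2 x K shares
  i_m <- (v_k - 1L) * 2L + 1L
  i_f <- (v_k - 1L) * 2L + 2L
  c11 <- ss$n11; c10 <- ss$n10; c01 <- ss$n01; c00 <- ss$n00
  cs1a <- ss$s1a; cs1u <- ss$s1u; cs2a <- ss$s2a; cs2u <- ss$s2u
  objective <- function(theta) {
    u <- unpack(theta)
    A <- u$A; C <- u$C
    Aown <- A[i_own]; Cown <- C[i_own]
    rho <- numeric(nr)
    rho[m_mzss] <- Aown[m_mzss] + Cown[m_mzss]
    rho[m_dzss] <- 0.5 * Aown[m_dzss] + Cown[m_dzss]
    kd <- v_k[m_dos]
    rd <- u$rho_dos[kd]
    rs <- 0.5 * sqrt(A[i_m[m_dos]] * A[i_f[m_dos]]) +
      u$rcdos[kd] * sqrt(C[i_m[m_dos]] * C[i_f[m_dos]])
    rho[m_dos] <- ifelse(is.na(rd), rs, rd)
    rho <- pmin(pmax(rho, -0.9999), 0.9999)
    t1 <- u$tau_flat[v_i1]
    t2 <- u$tau_flat[v_i2]
    p11 <- bvn_upper_tail(t1, t2, rho)
    m1 <- stats::pnorm(t1, lower.tail = FALSE)
    m2 <- stats::pnorm(t2, lower.tail = FALSE)
    p10 <- pmax(m1 - p11, 1e-300)
    p01 <- pmax(m2 - p11, 1e-300)
    p00 <- pmax(1 - m1 - m2 + p11, 1e-300)
    p11 <- pmax(p11, 1e-300)
    -2 * sum(c11 * log(p11) + c10 * log(p10) + c01 * log(p01) +
               c00 * log(p00) +
               cs1a * log(pmax(m1, 1e-300)) +
               cs1u * log(pmax(1 - m1, 1e-300)) +
               cs2a * log(pmax(m2, 1e-300)) +
               cs2u * log(pmax(1 - m2, 1e-300)))
  }
  # build a start vector from share matrices (2 x K), rcdos, tau
  make_start <- function(A, C, rcdos, tau_flat) {
    th <- numeric(ntheta)
    for (j in seq_along(classes)) {
      cell <- which(cm == classes[j])[1]
      sx <- (cell - 1) %% 2 + 1; kk <- (cell - 1) %/% 2 + 1
      a <- A[sx, kk]; cc <- C[sx, kk]
      if (!is.null(fix_class) && classes[j] == fix_class) {
        v <- fix$value
        blk <- switch(fix$comp,
          A = .qlogis_safe(cc / max(1 - v, 1e-9)),
          C = .qlogis_safe(a / max(1 - v, 1e-9)),
          E = .qlogis_safe(a / max(1 - v, 1e-9)))
        th[off_cls[j] + seq_len(npar_cls[j])] <- blk[seq_len(npar_cls[j])]
      } else if (is.na(spec$drop)) {
        th[off_cls[j] + 1:2] <- c(.qlogis_safe(a),
                                  .qlogis_safe(cc / max(1 - a, 1e-9)))
      } else if (spec$drop == "A") {
        th[off_cls[j] + 1] <- .qlogis_safe(cc)
      } else {
        th[off_cls[j] + 1] <- .qlogis_safe(a)
      }
    }
    if (n_rc) {
      rho_d <- 0.5 * sqrt(A[1, ] * A[2, ]) + rcdos * sqrt(C[1, ] * C[2, ])
      th[off_rc + seq_len(n_rc)] <-
        atanh(pmin(pmax(rho_d[rc_mask], -0.999), 0.999))
    }
    th[off_tau + seq_len(4L * K)] <- tau_flat
    th
  }
  list(objective = objective, unpack = unpack, make_start = make_start,
       ntheta = ntheta)
}

# deterministic default multi-start schedule on the (A, C) share scale
.ace_start_schedule <- list(
  c(A = 0.3, C = 0.3, rc = 0.8),
  c(A = 0.6, C = 0.2, rc = 0.5),
  c(A = 0.1, C = 0.5, rc = 1.0),
  c(A = 0.5, C = 0.1, rc = 0.9),
  c(A = 0.2, C = 0.2, rc = 0.3))

#' Fit an ACE model specification by full-information maximum likelihood
#'
#' Minimizes \eqn{-2\log L} over the spec's free parameters (shares per
#' equality class, Rcdos where free, and all sex x zygosity x cohort
#' thresholds) by quasi-Newton iterations from a fixed multi-start schedule,
#' so the fit is deterministic given data and spec. Singletons enter through
#' their marginal Bernoulli likelihood.
#'
#' @param ds A \code{twin_dataset}.
#' @param spec An \code{ace_model_spec} (see \code{\link{ace_model_spec}}).
#' @param start Optional \code{ace_params} used as an additional (first)
#'   start, e.g. a parent model's estimates.
#' @param n_starts Number of schedule starts to use (default 5;
#'   \code{start}, when given, is always tried first, and \code{n_starts =
#'   0} then skips the schedule entirely).
#' @return Object of class \code{ace_fit}: \code{spec}, \code{params}
#'   (an \code{ace_params}), \code{shares} (data frame of A/C/E per sex and
#'   cohort), \code{minus2LL}, \code{df}, \code{n_individuals},
#'   \code{convergence}.
#' @export
fit_ace <- function(ds, spec, start = NULL, n_starts = 5) {
  stopifnot(inherits(ds, "twin_dataset"), inherits(spec, "ace_model_spec"))
  cohorts <- attr(ds, "cohorts")
  if (length(cohorts) != spec$n_cohorts) {
    stop("dataset has ", length(cohorts), " cohort(s) but the spec expects ",
         spec$n_cohorts, call. = FALSE)
  }
  ss <- .ace_suffstats(ds)
  mach <- .ace_machine(ss, spec)
  K <- spec$n_cohorts
  tau0 <- .tau_start(ss, K)
  starts <- list()
  if (!is.null(start)) {
    stopifnot(inherits(start, "ace_params"))
    starts[[1]] <- mach$make_start(start$A, start$C,
                                   rep_len(start$rcdos, K),
                                   as.vector(start$tau))
  }
  n_sched <- min(max(n_starts, 0), 5)
  if (n_sched < 1 && !length(starts)) n_sched <- 1
  for (sch in .ace_start_schedule[seq_len(n_sched)]) {
    starts[[length(starts) + 1]] <- mach$make_start(
      matrix(sch["A"], 2, K), matrix(sch["C"], 2, K),
      rep(sch["rc"], K), tau0)
  }
  best <- NULL
  for (th0 in starts) {
    o <- stats::optim(th0, mach$objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  if (is.null(best)) stop("no successful optimization", call. = FALSE)
  u <- mach$unpack(best$par)
  E <- 1 - u$A - u$C
  rcdos <- u$rcdos
  free_rc <- is.na(rcdos)
  if (any(free_rc)) {
    # back out Rcdos from the directly fitted DOS correlation
    cc <- sqrt(u$C[1, ] * u$C[2, ])
    base <- 0.5 * sqrt(u$A[1, ] * u$A[2, ])
    rcdos[free_rc] <- ifelse(cc[free_rc] > 1e-8,
                             (u$rho_dos[free_rc] - base[free_rc]) /
                               cc[free_rc], 0)
  }
  params <- ace_params(u$A, u$C, E, rcdos, u$tau_flat, cohorts)
  shares <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(sex = c("M", "F"), cohort = cohorts[k],
               A = u$A[, k], C = u$C[, k], E = E[, k])
  }))
  rownames(shares) <- NULL
  n <- n_individuals(ds)
  structure(list(spec = spec, params = params, shares = shares,
                 minus2LL = best$value, df = model_df(spec, n),
                 n_individuals = n, convergence = best$convergence,
                 suffstats = ss),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE model %s: %s\n", x$spec$id, x$spec$description))
  cat(sprintf("-2LL = %.3f on df = %d (n = %d individuals)\n",
              x$minus2LL, x$df, x$n_individuals))
  print(transform(x$shares, A = round(A, 3), C = round(C, 3),
                  E = round(E, 3)))
  invisible(x)
}

#' Profile-likelihood confidence interval for a variance share or Rcdos
#'
#' The likelihood-based interval: the set of values of the component for
#' which the constrained \eqn{-2\log L} (all other free parameters
#' re-optimized) stays within the chi-square(1) critical increase (3.84 at
#' 95\%) of the minimum. Share intervals are truncated at [0, 1].
#'
#' @param fit An \code{ace_fit}.
#' @param component \code{"A"}, \code{"C"}, \code{"E"} or \code{"rcdos"}.
#' @param sex,cohort Identify the equality class (defaults to the first
#'   sex/cohort; irrelevant for fully equated models). For \code{"rcdos"},
#'   \code{cohort} selects the cohort.
#' @param conf Confidence level (default 0.95).
#' @return Numeric \code{c(low, high)}.
#' @export
profile_ci <- function(fit, component = c("A", "C", "E", "rcdos"),
                       sex = "M", cohort = NULL, conf = 0.95) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "ace_fit"))
  spec <- fit$spec
  ss <- fit$suffstats
  cohorts <- fit$params$cohorts
  if (is.null(cohort)) cohort <- cohorts[1]
  ki <- match(cohort, cohorts)
  crit <- fit$minus2LL + stats::qchisq(conf, df = 1)
  p <- fit$params
  if (component == "rcdos") {
    if (spec$rcdos != "free") stop("Rcdos is fixed in this model")
    pdev <- function(v) {
      # pin cohort `ki` at v, leave the other cohorts' rcdos free
      mach <- .ace_machine(ss, spec, rcdos_fix = {
        rc <- rep(NA_real_, length(cohorts)); rc[ki] <- v; rc
      })
      th0 <- mach$make_start(p$A, p$C, p$rcdos, as.vector(p$tau))
      stats::optim(th0, mach$objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))$value
    }
    hat <- p$rcdos[[ki]]
    lo <- .profile_scan(pdev, hat, crit, dir = -1, lim = -Inf)
    hi <- .profile_scan(pdev, hat, crit, dir = +1, lim = Inf)
    return(c(lo, hi))
  }
  cls <- spec$class_map[match(sex, c("M", "F")), ki]
  hat <- fit$shares[[component]][fit$shares$sex == sex &
                                   fit$shares$cohort == cohort]
  make_pdev <- function() {
    last <- NULL  # warm-start chain across nearby fixed values
    function(v) {
      mach <- .ace_machine(ss, spec, fix_class = cls,
                           fix = list(comp = component, value = v))
      th0 <- if (!is.null(last)) last else {
        mach$make_start(p$A, p$C, p$rcdos, as.vector(p$tau))
      }
      o <- stats::optim(th0, mach$objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-11))
      last <<- o$par
      o$value
    }
  }
  lo <- .profile_root(make_pdev(), hat, crit, lower = TRUE, lim = 0,
                      tol = 1e-3)
  hi <- .profile_root(make_pdev(), hat, crit, lower = FALSE, lim = 1,
                      tol = 1e-3)
  c(max(lo, 0), min(hi, 1))
}

# outward scan + uniroot for unbounded components (Rcdos)
.profile_scan <- function(pdev, hat, crit, dir, lim, step = 0.2,
                          max_steps = 25) {
  v <- hat
  for (i in seq_len(max_steps)) {
    v2 <- v + dir * step
    if ((dir < 0 && v2 < lim) || (dir > 0 && v2 > lim)) return(lim)
    if (pdev(v2) > crit) {
      a <- v; b <- v2
      for (j in 1:50) {
        if (abs(b - a) < 1e-4) break
        m <- (a + b) / 2
        if (pdev(m) > crit) b <- m else a <- m
      }
      return((a + b) / 2)
    }
    v <- v2
  }
  dir * Inf
}

#' Saturated-correlation fit (one free correlation per group and cohort)
#'
#' Fits a free liability correlation for every zygosity-sex group in every
#' cohort, with free thresholds per group (same-sex groups share one
#' threshold across co-twins; DOS has male and female thresholds), through
#' the same FIML machinery as the structural models. On complete-pair data
#' this is the exact joint-ML analogue of the per-group tetrachoric
#' estimates.
#'
#' @param ds A \code{twin_dataset}.
#' @return List with \code{correlations} (data frame: cohort, group, r,
#'   tau1, tau2), \code{minus2LL}, \code{n_free_params}.
#' @export
fit_saturated <- function(ds) {
  ss <- .ace_suffstats(ds)
  n <- nrow(ss)
  dos <- ss$group == "DOS"
  ntau <- ifelse(dos, 2L, 1L)
  off_tau <- n + cumsum(c(0L, ntau))[seq_len(n)]
  ntheta <- n + sum(ntau)
  row_tau <- function(theta, i) {
    if (dos[i]) theta[off_tau[i] + 1:2] else rep(theta[off_tau[i] + 1], 2)
  }
  objective <- function(theta) {
    d <- 0
    for (i in seq_len(n)) {
      tt <- row_tau(theta, i)
      d <- d + .tetra_dev(tanh(theta[i]), tt[1], tt[2], ss[i, ])
    }
    d
  }
  th0 <- numeric(ntheta)
  tau0 <- .tau_start(ss, max(ss$k))
  for (i in seq_len(n)) {
    th0[i] <- atanh(0.3)
    th0[off_tau[i] + seq_len(ntau[i])] <-
      if (dos[i]) tau0[c(ss$i1[i], ss$i2[i])] else tau0[ss$i1[i]]
  }
  o <- stats::optim(th0, objective, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-12))
  taus <- t(vapply(seq_len(n), function(i) row_tau(o$par, i), numeric(2)))
  list(correlations = data.frame(cohort = ss$cohort, group = ss$group,
                                 r = tanh(o$par[seq_len(n)]),
                                 tau1 = taus[, 1], tau2 = taus[, 2]),
       minus2LL = o$value, n_free_params = ntheta,
       convergence = o$convergence)
}
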