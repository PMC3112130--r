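# Numerics of the liability-threshold model: normal thresholds, bivariate
# normal orthant probabilities, and the Falconer moment decomposition.

#' Liability threshold from a prevalence
#'
#' Under the liability-threshold model a binary trait is the dichotomization
#' of a latent standard-normal liability: an individual is affected when the
#' liability exceeds the threshold \eqn{\tau}, so \eqn{P(\mathrm{affected}) =
#' 1 - \Phi(\tau)}. This returns the threshold matching a given prevalence.
#'
#' @param prev Prevalence (proportion affected), strictly inside (0, 1).
#'   Vectorized.
#' @return Threshold(s) in standard-normal units.
#' @examples
#' threshold_from_prevalence(0.5)    # 0
#' threshold_from_prevalence(0.228)  # about 0.745
#' @export
threshold_from_prevalence <- function(prev) {
  if (!is.numeric(prev) || any(!is.finite(prev)) ||
      any(prev <= 0) || any(prev >= 1)) {
    stop("'prev' must be a proportion strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(prev, lower.tail = FALSE)
}

# 20-point Gauss-Legendre rule on [-1, 1] (positive half; the code mirrors
# the nodes), used by the orthant-probability quadrature below.
.gl20 <- list(
  x = c(0.07652652113349733, 0.22778585114164507, 0.37370608871541956,
        0.51086700195082710, 0.63605368072651503, 0.74633190646015079,
        0.83911697182221882, 0.91223442825132591, 0.96397192727791379,
        0.99312859918509492),
  w = c(0.15275338713072585, 0.14917298647260375, 0.14209610931838205,
        0.13168863844917663, 0.11819453196151842, 0.10193011981724044,
        0.08327674157670475, 0.06267204833410907, 0.04060142980038694,
        0.01761400713915212))

#' Standard bivariate normal upper-tail probability
#'
#' Computes \eqn{P(X > \tau_1, Y > \tau_2)} for a standard bivariate normal
#' vector with correlation \eqn{\rho}, using the Drezner-Wesolowsky style
#' Gauss-Legendre quadrature with the high-correlation reformulation of
#' Genz; absolute accuracy is well below 1e-10 over the whole domain.
#' Correlations within 1e-12 of \eqn{\pm 1} short-circuit to the degenerate
#' closed forms so that likelihoods stay finite near boundary correlations.
#'
#' @param tau1,tau2 Thresholds (standard-normal units). Vectorized.
#' @param rho Correlation(s) in \eqn{[-1, 1]}.
#' @return Probability vector, same length as the recycled inputs.
#' @examples
#' bvn_upper_tail(0, 0, 0)     # 0.25
#' bvn_upper_tail(0, 0, 0.5)   # 1/4 + asin(0.5) / (2*pi)
#' @export
bvn_upper_tail <- function(tau1, tau2, rho) {
  n <- max(length(tau1), length(tau2), length(rho))
  h <- rep_len(as.numeric(tau1), n)
  k <- rep_len(as.numeric(tau2), n)
  r <- rep_len(as.numeric(rho), n)
  if (any(!is.finite(h)) || any(!is.finite(k)) || any(!is.finite(r)) ||
      any(abs(r) > 1)) {
    stop("thresholds must be finite and |rho| <= 1", call. = FALSE)
  }
  out <- numeric(n)

  hi <- abs(r) >= 1 - 1e-12
  if (any(hi)) {
    pos <- hi & r > 0
    neg <- hi & r < 0
    # comonotone: X = Y; antithetic: Y = -X
    out[pos] <- stats::pnorm(pmax(h[pos], k[pos]), lower.tail = FALSE)
    out[neg] <- pmax(0, stats::pnorm(-k[neg]) - stats::pnorm(h[neg]))
  }

  mid <- !hi & abs(r) < 0.925
  if (any(mid)) {
    hh <- h[mid]; kk <- k[mid]; rr <- r[mid]
    asr <- asin(rr)
    hs <- (hh * hh + kk * kk) / 2
    hk <- hh * kk
    # theta-substitution of the BVN density integral over the correlation
    acc <- numeric(sum(mid))
    for (j in seq_along(.gl20$x)) {
      for (s in c(-1, 1)) {
        sn <- sin(asr * (s * .gl20$x[j] + 1) / 2)
        acc <- acc + .gl20$w[j] * exp((sn * hk - hs) / (1 - sn * sn))
      }
    }
    out[mid] <- acc * asr / (4 * pi) +
      stats::pnorm(-hh) * stats::pnorm(-kk)
  }

  edge <- !hi & !mid
  if (any(edge)) {
    out[edge] <- vapply(which(edge), function(i) .bvnu_highcorr(h[i], k[i], r[i]),
                        numeric(1))
  }
  pmin(pmax(out, 0), 1)
}

# High-|rho| branch (0.925 <= |rho| < 1): Genz reformulation integrating the
# difference from the perfectly correlated case, with an analytic expansion
# for the near-singular part. Scalar.
.bvnu_highcorr <- function(h, k, r) {
  if (r < 0) {
    k <- -k
  }
  hk <- h * k
  bvn <- 0
  as_ <- (1 - r) * (1 + r)
  a <- sqrt(as_)
  bs <- (h - k)^2
  cc <- (4 - hk) / 8
  d <- (12 - hk) / 16
  asr <- -(bs / as_ + hk) / 2
  if (asr > -100) {
    bvn <- a * exp(asr) *
      (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
  }
  if (-hk < 100) {
    b <- sqrt(bs)
    sp <- sqrt(2 * pi) * stats::pnorm(-b / a)
    bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
  }
  a2 <- a / 2
  for (j in seq_along(.gl20$x)) {
    for (s in c(-1, 1)) {
      xs <- (a2 * (s * .gl20$x[j] + 1))^2
      rs <- sqrt(1 - xs)
      asr1 <- -(bs / xs + hk) / 2
      if (asr1 > -100) {
        sp <- 1 + cc * xs * (1 + d * xs)
        ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
        bvn <- bvn + a2 * .gl20$w[j] * exp(asr1) * (ep - sp)
      }
    }
  }
  bvn <- -bvn / (2 * pi)
  if (r > 0) {
    bvn <- bvn + stats::pnorm(-max(h, k))
  } else {
    bvn <- -bvn
    if (k > h) bvn <- bvn + stats::pnorm(k) - stats::pnorm(h)
  }
  bvn
}

#' Joint cell probabilities of a dichotomized bivariate liability
#'
#' Probabilities of the four joint outcomes (both affected, first only,
#' second only, neither) when two standard-normal liabilities with
#' correlation \eqn{\rho} are dichotomized at thresholds \eqn{\tau_1},
#' \eqn{\tau_2}.
#'
#' @inheritParams bvn_upper_tail
#' @return Named list with elements \code{p11}, \code{p10}, \code{p01},
#'   \code{p00} (vectors when the inputs are vectors); margins are exact by
#'   construction.
#' @export
cell_probabilities <- function(tau1, tau2, rho) {
  p11 <- bvn_upper_tail(tau1, tau2, rho)
  m1 <- stats::pnorm(tau1, lower.tail = FALSE)
  m2 <- stats::pnorm(tau2, lower.tail = FALSE)
  p10 <- pmax(m1 - p11, 0)
  p01 <- pmax(m2 - p11, 0)
  p00 <- pmax(1 - m1 - m2 + p11, 0)
  list(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}

#' Falconer moment decomposition of twin correlations
#'
#' The classical moment estimator of the ACE variance shares from MZ and DZ
#' liability correlations: \eqn{A = 2(r_{MZ} - r_{DZ})}, \eqn{C = 2 r_{DZ} -
#' r_{MZ}}, \eqn{E = 1 - r_{MZ}}. Components are returned as-is (not
#' truncated to \eqn{[0,1]}); an attribute \code{"negative"} flags estimates
#' outside the parameter space. This is an algebraic cross-check of the
#' likelihood-based decomposition, not a substitute for it.
#'
#' @param r_mz,r_dz MZ and DZ twin correlations, with \code{r_dz <= r_mz}.
#' @return Named numeric vector \code{c(A =, C =, E =)} summing to 1.
#' @examples
#' falconer_decompose(0.80, 0.47)  # A = .66, C = .14, E = .20
#' @export
falconer_decompose <- function(r_mz, r_dz) {
  stopifnot(is.numeric(r_mz), is.numeric(r_dz),
            r_mz >= -1, r_mz <= 1, r_dz >= -1, r_dz <= 1)
  if (r_dz > r_mz) {
    warning("r_dz exceeds r_mz; the A component will be negative")
  }
  out <- c(A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz, E = 1 - r_mz)
  attr(out, "negative") <- any(out < 0)
  out
}
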