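#' Two-state Boltzmann dissipation curve
#'
#' The sigmoid model of the cumulative dissipation curve:
#' \deqn{NR(t) = NR_2 + \frac{NR_1 - NR_2}{1 + e^{(t - t_0)/dt}}}
#' with lower asymptote `NR1` (initial number of affected residues),
#' upper asymptote `NR2` (final number), centre `t0` (the half response
#' time) and time constant `dt`.
#'
#' @param t time(s), fs.
#' @param NR1 initial number of affected residues.
#' @param NR2 final number of affected residues.
#' @param t0 half response time, fs.
#' @param dt time constant, fs (> 0).
#' @return real-valued residue count(s).
#' @export
boltzmann_nr <- function(t, NR1, NR2, t0, dt) {
  ed_assert(dt > 0, "enerdiss_domain_error", "dt must be > 0")
  NR2 + (NR1 - NR2) / (1 + exp((t - t0) / dt))
}

#' Dissipation rate constant
#'
#' The first derivative of the two-state Boltzmann curve at its centre
#' (t0, (NR1+NR2)/2), in closed form:
#' \deqn{NR' = \frac{NR_2 - NR_1}{4\,dt}}
#' It measures how many residues respond per fs during the exponential
#' stage and is insensitive to the perturbation strength.
#'
#' @inheritParams boltzmann_nr
#' @return rate in residues per fs.
#' @export
dissipation_rate_constant <- function(NR1, NR2, dt) {
  ed_assert(dt > 0, "enerdiss_domain_error", "dt must be > 0")
  (NR2 - NR1) / (4 * dt)
}

#' Lorentzian difference-curve model
#'
#' The peak model for a variant-minus-wild-type difference curve:
#' \deqn{\Delta NR(t) = NR_0 + \frac{2A}{\pi}\,
#'   \frac{w}{4 (t - t_c)^2 + w^2}}
#' with offset `NR0`, peak time `tc`, width `w` and area `A`; the peak
#' height is given by [lorentz_height()].
#'
#' @param t time(s), fs.
#' @param NR0 offset, residues.
#' @param tc peak time, fs.
#' @param w peak width, fs (> 0).
#' @param A area under the peak, fs * residues.
#' @return real-valued residue-count change(s).
#' @export
lorentz_delta <- function(t, NR0, tc, w, A) {
  ed_assert(w > 0, "enerdiss_domain_error", "w must be > 0")
  NR0 + (2 * A / pi) * w / (4 * (t - tc)^2 + w^2)
}

#' Lorentzian peak height
#'
#' The value of the Lorentzian model at its peak time:
#' \deqn{h = NR_0 + \frac{2A}{\pi w}}
#' Used as a proxy for how strongly a variant perturbs the dissipation
#' process relative to the wild-type.
#'
#' @inheritParams lorentz_delta
#' @return height in residues.
#' @export
lorentz_height <- function(NR0, w, A) {
  ed_assert(w > 0, "enerdiss_domain_error", "w must be > 0")
  NR0 + 2 * A / (pi * w)
}

#' Adjusted coefficient of determination
#'
#' @param ss_res residual sum of squares.
#' @param ss_tot total sum of squares (> 0).
#' @param n number of data points.
#' @param p number of free parameters.
#' @return adjusted R^2 = 1 - (ss_res/ss_tot) * (n-1)/(n-p-1).
#' @export
adjusted_r2 <- function(ss_res, ss_tot, n, p) {
  ed_assert(n > p + 1, "enerdiss_domain_error", "need n > p + 1")
  ed_assert(ss_tot > 0, "enerdiss_domain_error", "ss_tot must be > 0")
  1 - (ss_res / ss_tot) * (n - 1) / (n - p - 1)
}

# shared nls post-processing: SEs, adjusted R2
.fit_stats <- function(fit, y, p) {
  sm <- summary(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(se = sm$coefficients[, "Std. Error"],
       adj_R2 = adjusted_r2(ss_res, ss_tot, length(y), p),
       ss_res = ss_res, n = length(y))
}

#' Fit the two-state Boltzmann model to a dissipation curve
#'
#' Unweighted nonlinear least squares for (t0, dt) with the asymptotes
#' NR1 and NR2 held fixed (NR1 = number of perturbed residues, NR2 =
#' total residue count, both known by construction).  Standard errors
#' come from the asymptotic covariance; the dissipation rate constant is
#' recomputed from the fitted dt.
#'
#' @param curve a `dissipation_curve`, or any data.frame/list with
#'   elements `t` and `NR`.
#' @param NR1 lower asymptote; defaults to the curve's recorded perturbed
#'   count, else 1.
#' @param NR2 upper asymptote (no default unless the curve saturates).
#' @return a `boltzmann_fit`: list with NR1, NR2, t0, dt, their SEs,
#'   NRprime, adj_R2, n and the fitted object.
#' @export
fit_boltzmann <- function(curve, NR1 = NULL, NR2 = NULL) {
  t <- as.numeric(curve$t); y <- as.numeric(curve$NR)
  ed_assert(length(t) >= 5, "enerdiss_fit_error",
            "need at least 5 curve points")
  if (is.null(NR1)) NR1 <- if (!is.null(attr(curve, "NR1")))
    attr(curve, "NR1") else 1
  if (is.null(NR2)) NR2 <- max(y)
  ed_assert(NR2 > NR1, "enerdiss_fit_error", "NR2 must exceed NR1")
  if (max(y) - min(y) == 0) {
    ed_stop("enerdiss_fit_error",
            "degenerate (constant) curve: nothing to fit")
  }
  mid <- (NR1 + NR2) / 2
  t0_init <- t[which.min(abs(y - mid))]
  # logistic quartile crossings: t0 +/- dt*log(3)
  q1 <- NR1 + 0.25 * (NR2 - NR1); q3 <- NR1 + 0.75 * (NR2 - NR1)
  t25 <- t[which.min(abs(y - q1))]; t75 <- t[which.min(abs(y - q3))]
  dt_init <- max((t75 - t25) / (2 * log(3)), diff(range(t)) / 50)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ NR2 + (NR1 - NR2) / (1 + exp((t - t0) / dt)),
               data = dat, start = list(t0 = t0_init, dt = dt_init),
               algorithm = "port",
               lower = c(t0 = -Inf, dt = 1e-9),
               control = stats::nls.control(maxiter = 200,
                                            tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) {
      ed_stop("enerdiss_fit_error",
              "Boltzmann fit did not converge (init t0=%.6g, dt=%.6g): %s",
              t0_init, dt_init, conditionMessage(e))
    })
  est <- stats::coef(fit)
  st <- .fit_stats(fit, y, p = 2)
  structure(list(NR1 = NR1, NR2 = NR2,
                 t0 = unname(est["t0"]), dt = unname(est["dt"]),
                 t0_se = unname(st$se["t0"]), dt_se = unname(st$se["dt"]),
                 NRprime = dissipation_rate_constant(NR1, NR2,
                                                     unname(est["dt"])),
                 adj_R2 = st$adj_R2, n = st$n, fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Two-state Boltzmann fit (NR1 = %g, NR2 = %g fixed)\n",
    "  t0 (half response time): %.1f +/- %.1f fs\n",
    "  dt (time constant):      %.1f +/- %.1f fs\n",
    "  NR' (dissipation rate):  %.1f residues/fs\n",
    "  adj-R2: %.3f  (n = %d)\n"),
    x$NR1, x$NR2, x$t0, x$t0_se, x$dt, x$dt_se, x$NRprime, x$adj_R2, x$n))
  invisible(x)
}

#' Fit the Lorentzian model to a variant difference curve
#'
#' Unweighted nonlinear least squares for (NR0, tc, w, A).
#' Initialization: the offset from the median of the curve's tails, the
#' peak time from the extremum of a lightly smoothed copy, the width from
#' the half-height width around the peak, and the area from height *
#' width * pi / 2.
#'
#' @param diff a difference curve: data.frame/list with `t` and `dNR`.
#' @return a `lorentz_fit`: NR0, tc, w, A with SEs, peak height h,
#'   adj_R2, n and the fitted object.
#' @export
fit_lorentz <- function(diff) {
  t <- as.numeric(diff$t); y <- as.numeric(diff$dNR)
  ed_assert(length(t) >= 6, "enerdiss_fit_error",
            "need at least 6 curve points")
  # light moving-average smoothing for initialization only
  k <- min(5L, length(y) - (1 - length(y) %% 2))
  sm <- if (k >= 3) as.numeric(stats::filter(y, rep(1 / k, k),
                                             sides = 2)) else y
  sm[is.na(sm)] <- y[is.na(sm)]
  ntail <- max(3L, length(y) %/% 10)
  nr0_init <- stats::median(c(utils::head(y, ntail),
                              utils::tail(y, ntail)))
  dev <- sm - nr0_init
  if (max(abs(dev)) < 1e-12 || stats::sd(y) < 1e-12) {
    ed_stop("enerdiss_fit_error",
            "flat difference curve: no detectable peak")
  }
  pk <- which.max(abs(dev))
  ed_assert(pk > 1 && pk < length(y), "enerdiss_fit_error",
            "no interior extremum: peak sits on the window edge")
  h_init <- sm[pk]
  half <- abs(dev[pk]) / 2
  lo <- pk; while (lo > 1 && abs(dev[lo]) > half) lo <- lo - 1
  hi <- pk; while (hi < length(y) && abs(dev[hi]) > half) hi <- hi + 1
  w_init <- max(t[hi] - t[lo], diff(range(t)) / 50)
  a_init <- (h_init - nr0_init) * w_init * pi / 2
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ NR0 + (2 * A / pi) * w / (4 * (t - tc)^2 + w^2),
               data = dat,
               start = list(NR0 = nr0_init, tc = t[pk], w = w_init,
                            A = a_init),
               algorithm = "port",
               lower = c(NR0 = -Inf, tc = -Inf, w = 1e-9, A = -Inf),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) {
      ed_stop("enerdiss_fit_error",
              "Lorentz fit did not converge (init NR0=%.4g, tc=%.4g, w=%.4g, A=%.4g): %s",
              nr0_init, t[pk], w_init, a_init, conditionMessage(e))
    })
  est <- stats::coef(fit)
  if (est["w"] <= 2e-9) {
    ed_stop("enerdiss_fit_error", "width stuck at its lower bound")
  }
  st <- .fit_stats(fit, y, p = 4)
  structure(list(NR0 = unname(est["NR0"]), tc = unname(est["tc"]),
                 w = unname(est["w"]), A = unname(est["A"]),
                 NR0_se = unname(st$se["NR0"]), tc_se = unname(st$se["tc"]),
                 w_se = unname(st$se["w"]), A_se = unname(st$se["A"]),
                 h = lorentz_height(unname(est["NR0"]), unname(est["w"]),
                                    unname(est["A"])),
                 adj_R2 = st$adj_R2, n = st$n, fit = fit),
            class = "lorentz_fit")
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Lorentzian peak fit\n",
    "  NR0 (offset):    %.1f +/- %.1f residues\n",
    "  tc  (peak time): %.1f +/- %.1f fs\n",
    "  w   (width):     %.1f +/- %.1f fs\n",
    "  A   (area):      %.1f +/- %.1f fs*residues\n",
    "  h   (height):    %.1f residues\n",
    "  adj-R2: %.3f  (n = %d)\n"),
    x$NR0, x$NR0_se, x$tc, x$tc_se, x$w, x$w_se, x$A, x$A_se,
    x$h, x$adj_R2, x$n))
  invisible(x)
}

#' Export a fit as a plain list for JSON reports
#' @param fit a `boltzmann_fit` or `lorentz_fit`.
#' @return a named list without the internal nls object.
#' @export
fit_report <- function(fit) {
  out <- unclass(fit)
  out$fit <- NULL
  out$model <- if (inherits(fit, "boltzmann_fit")) "two-state Boltzmann"
               else "Lorentzian peak"
  out
}
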