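#' Fit first-order inactivation kinetics
#'
#' Fits the exponential activity-decay model `A_t = A_0 * exp(-k_in * t)`
#' by Levenberg-Marquardt nonlinear least squares. Initial guesses come
#' from a log-linear regression on the positive activities; two perturbed
#' restarts guard against poor starts and the best (lowest-SSR) converged
#' fit is kept. `k_in` is constrained non-negative.
#'
#' @param decay_data Tibble/data frame with columns `time` (min,
#'   non-negative, strictly increasing) and `activity` (arbitrary activity
#'   units); at least 4 points.
#' @return Object of class `phstab_infit` with [tidy()]/[glance()] methods;
#'   elements `k_in`, `A_0`, their standard errors, and `r_squared`.
#' @export
#' @examples
#' d <- gen_decay(k_in = 0.01, noise_sd = 0, seed = 1)
#' fit_inactivation(d)$k_in
fit_inactivation <- function(decay_data) {
  d <- tibble::as_tibble(decay_data)
  stopifnot(all(c("time", "activity") %in% names(d)))
  if (nrow(d) < 4) abort("need at least 4 points to fit a decay")
  if (any(d$time < 0) || any(diff(d$time) <= 0)) {
    abort("times must be non-negative and strictly increasing")
  }
  if (all(d$activity <= 0)) abort("non-positive activities: nothing to fit")

  pos <- d$activity > 0
  ll <- stats::lm(log(activity) ~ time, data = d[pos, , drop = FALSE])
  k0 <- max(-unname(coef(ll)[2]), 0)
  a0 <- exp(unname(coef(ll)[1]))
  starts <- list(
    c(A_0 = a0, k_in = k0),
    c(A_0 = a0 * 1.2, k_in = max(k0 * 2, 1e-6)),
    c(A_0 = a0 * 0.8, k_in = k0 / 2)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        activity ~ A_0 * exp(-k_in * time),
        data = d, start = as.list(st),
        lower = c(A_0 = 1e-12, k_in = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) abort("inactivation fit failed to converge from all starts")
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) setNames(rep(NA_real_, 2), names(est))
  )
  tss <- sum((d$activity - mean(d$activity))^2)
  structure(
    list(
      k_in = unname(est["k_in"]), A_0 = unname(est["A_0"]),
      k_in_se = unname(se["k_in"]), A_0_se = unname(se["A_0"]),
      r_squared = if (tss > 0) 1 - best$ssr / tss else 1,
      n = nrow(d), fit = fit, data = d
    ),
    class = "phstab_infit"
  )
}

#' @export
print.phstab_infit <- function(x, ...) {
  cat(sprintf(
    "<phstab_infit> k_in = %.4g min^-1 (SE %.2g), A_0 = %.4g (SE %.2g), R^2 = %.4f\n",
    x$k_in, x$k_in_se, x$A_0, x$A_0_se, x$r_squared
  ))
  invisible(x)
}

#' Fit Michaelis-Menten kinetics
#'
#' Fits `v = k_cat * E_0 * S / (K_M + S)` to initial-rate data by
#' Levenberg-Marquardt least squares. Initial guesses: `K_M = median(S)`,
#' `V_max = max(v)`; perturbed restarts as in [fit_inactivation()]. A
#' warning is issued when the substrate grid leaves `K_M` poorly
#' constrained (fitted `K_M` far outside the sampled range).
#'
#' @param mm_data Tibble/data frame with columns `substrate` (uM, > 0) and
#'   `rate` (uM/s, or any rate unit); at least 5 points.
#' @param enzyme_conc Total enzyme concentration `E_0` in uM (default 1, in
#'   which case `k_cat` absorbs the scale of the rates).
#' @return Object of class `phstab_mmfit` with `k_cat`, `K_M`, standard
#'   errors, `efficiency` (`k_cat / K_M`) and [tidy()]/[glance()] methods.
#' @export
fit_michaelis_menten <- function(mm_data, enzyme_conc = 1) {
  d <- tibble::as_tibble(mm_data)
  stopifnot(all(c("substrate", "rate") %in% names(d)))
  if (nrow(d) < 5) abort("need at least 5 points to fit Michaelis-Menten")
  if (any(d$substrate <= 0)) abort("substrate concentrations must be > 0")

  km0 <- stats::median(d$substrate)
  vmax0 <- max(d$rate)
  starts <- list(
    c(k_cat = vmax0 / enzyme_conc, K_M = km0),
    c(k_cat = 2 * vmax0 / enzyme_conc, K_M = km0 * 3),
    c(k_cat = 1.1 * vmax0 / enzyme_conc, K_M = km0 / 3)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ k_cat * enzyme_conc * substrate / (K_M + substrate),
        data = d, start = as.list(st),
        lower = c(k_cat = 1e-12, K_M = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) abort("Michaelis-Menten fit failed to converge from all starts")
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) setNames(rep(NA_real_, 2), names(est))
  )
  if (est["K_M"] > 5 * max(d$substrate) || est["K_M"] < min(d$substrate) / 5) {
    warn("K_M poorly constrained: fitted value far outside the sampled substrate range")
  }
  tss <- sum((d$rate - mean(d$rate))^2)
  structure(
    list(
      k_cat = unname(est["k_cat"]), K_M = unname(est["K_M"]),
      k_cat_se = unname(se["k_cat"]), K_M_se = unname(se["K_M"]),
      efficiency = unname(est["k_cat"] / est["K_M"]),
      enzyme_conc = enzyme_conc,
      r_squared = if (tss > 0) 1 - best$ssr / tss else 1,
      n = nrow(d), fit = fit, data = d
    ),
    class = "phstab_mmfit"
  )
}

#' @export
print.phstab_mmfit <- function(x, ...) {
  cat(sprintf(
    "<phstab_mmfit> k_cat = %.4g s^-1 (SE %.2g), K_M = %.4g uM (SE %.2g), k_cat/K_M = %.2g\n",
    x$k_cat, x$k_cat_se, x$K_M, x$K_M_se, x$efficiency
  ))
  invisible(x)
}

#' Catalytic efficiency k_cat / K_M
#'
#' @param fit A `phstab_mmfit`, or a numeric `k_cat` (then `K_M` must be
#'   given).
#' @param K_M Michaelis constant, uM (when `fit` is numeric).
#' @return Efficiency in uM^-1 s^-1 (reports conventionally round this to
#'   2 significant figures).
#' @export
#' @examples
#' catalytic_efficiency(25.0, 25.0) # 1
catalytic_efficiency <- function(fit, K_M = NULL) {
  if (inherits(fit, "phstab_mmfit")) {
    return(fit$k_cat / fit$K_M)
  }
  stopifnot(is.numeric(fit), !is.null(K_M))
  if (fit == 0) {
    return(0)
  }
  fit / K_M
}

#' Stabilization fold-change between two inactivation constants
#'
#' Ratio of the reference (e.g. wild-type) inactivation constant to the
#' variant's: how many times slower the variant inactivates.
#'
#' @param k_in_reference,k_in_variant Inactivation constants (min^-1, > 0),
#'   or `phstab_infit` objects.
#' @return Fold change (dimensionless).
#' @export
#' @examples
#' stabilization_fold(0.0026, 0.00029) # ~9-fold
stabilization_fold <- function(k_in_reference, k_in_variant) {
  k1 <- if (inherits(k_in_reference, "phstab_infit")) k_in_reference$k_in else k_in_reference
  k2 <- if (inherits(k_in_variant, "phstab_infit")) k_in_variant$k_in else k_in_variant
  if (k2 <= 0) abort("variant inactivation constant must be > 0")
  if (k1 <= 0) abort("reference inactivation constant must be > 0")
  k1 / k2
}
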