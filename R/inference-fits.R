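#' Fit result container
#'
#' Uniform return type of the assay fitters: point estimates of the
#' effective constants, standard errors where available, and honest
#' diagnostics (present even when the fit fails or is degenerate).
#'
#' @param estimates Named list/vector of estimates.
#' @param se Named standard errors (NA when unavailable).
#' @param converged Logical convergence flag.
#' @param residual_norm Residual norm of the fit.
#' @param flags Character vector of quality flags (e.g. `"unreliable_se"`,
#'   `"non_identifiable"`, `"degenerate"`).
#' @return A `fit_result` object.
#' @export
fit_result <- function(estimates, se = NULL, converged = TRUE,
                       residual_norm = NA_real_, flags = character()) {
  structure(list(estimates = estimates, se = se, converged = converged,
                 residual_norm = residual_norm, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (converged:", x$converged, ")\n")
  est <- unlist(x$estimates)
  est <- est[!is.na(suppressWarnings(as.numeric(est)))]
  for (nm in names(est)) {
    se <- if (!is.null(x$se) && nm %in% names(x$se)) x$se[[nm]] else NA
    cat(sprintf("  %s = %g (se %g)\n", nm, as.numeric(est[[nm]]), se))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood off-rate from bond lifetimes
#'
#' For i.i.d. exponential lifetimes the MLE of the dissociation rate is the
#' inverse sample mean, with standard error `estimate/sqrt(n)`.
#'
#' @param sample A `lifetime_sample` (or numeric vector of durations).
#' @return A [fit_result()] with estimate `k_off`; a single observation is
#'   fitted but its standard error is flagged unreliable.
#' @export
fit_lifetimes <- function(sample) {
  durations <- if (inherits(sample, "lifetime_sample")) sample$durations else sample
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all bond durations must be positive", call. = FALSE)
  }
  n <- length(durations)
  k_off <- 1 / mean(durations)
  flags <- if (n < 2L) "unreliable_se" else character()
  fit_result(estimates = list(k_off = k_off),
             se = c(k_off = k_off / sqrt(n)),
             converged = TRUE, residual_norm = 0, flags = flags)
}

#' Fit a two-phase 1:1 model to an SPR sensorgram
#'
#' Nonlinear least squares (Levenberg-Marquardt, log-parameterized) of the
#' closed-form association/dissociation signal to the sensorgram, estimating
#' `k_on`, `k_off` and `R_max`. Starting values come from the dissociation
#' tail (log-linear decay) and the association amplitude. A flat or
#' signal-free sensorgram is returned with `k_on = 0` and flagged degenerate
#' rather than erroring.
#'
#' @param sg A `sensorgram` from [synthesize_sensorgram()] (attributes carry
#'   the phase schedule), or a data frame with `time`, `signal`, `conc` plus
#'   arguments `t_assoc`.
#' @param t_assoc Association-phase duration; defaults to the generator
#'   attribute.
#' @return A [fit_result()] whose `estimates` hold an SS 3D
#'   [effective_constants()] plus `R_max`.
#' @export
fit_sensorgram <- function(sg, t_assoc = attr(sg, "t_assoc")) {
  if (is.null(t_assoc)) stop("association-phase duration required", call. = FALSE)
  if (max(sg$time) <= t_assoc) {
    stop("both association and dissociation phases are required", call. = FALSE)
  }
  conc_assoc <- max(sg$conc)
  peak <- max(abs(sg$signal))
  if (conc_assoc == 0 || peak == 0 ||
      stats::sd(sg$signal) < 1e-12 * max(peak, 1)) {
    return(fit_result(estimates = list(k_on = 0, k_off = NA_real_,
                                       R_max = NA_real_),
                      converged = FALSE, residual_norm = 0,
                      flags = "degenerate"))
  }
  ## start values: k_off from the log-linear dissociation tail
  dis <- sg[sg$time > t_assoc & sg$signal > 0.05 * peak, ]
  k_off0 <- if (nrow(dis) >= 3L) {
    max(-stats::coef(stats::lm(log(signal) ~ time, data = dis))[[2L]], 1e-4)
  } else 0.1
  B1 <- sg$signal[which.min(abs(sg$time - t_assoc))]
  R_max0 <- max(2 * B1, peak)
  k_on0 <- max(k_off0 / conc_assoc * B1 / max(R_max0 - B1, 0.05 * R_max0), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ spr_signal(time, exp(lkon), exp(lkoff), conc_assoc, t_assoc,
                          exp(lRmax)),
      data = sg,
      start = list(lkon = log(k_on0), lkoff = log(k_off0),
                   lRmax = log(R_max0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(estimates = list(k_on = k_on0, k_off = k_off0,
                                       R_max = R_max0),
                      converged = FALSE, residual_norm = NA_real_,
                      flags = "non_convergence"))
  }
  cf <- exp(stats::coef(fit))
  names(cf) <- c("k_on", "k_off", "R_max")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"] * cf,
                 error = function(e) rep(NA_real_, 3L))
  names(se) <- names(cf)
  fit_result(
    estimates = list(
      eff = effective_constants("SS", "3D", k_on = cf[["k_on"]],
                                k_off = cf[["k_off"]]),
      R_max = cf[["R_max"]]),
    se = se, converged = fit$convInfo$isConv %||% TRUE,
    residual_norm = sqrt(sum(stats::resid(fit)^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the single-step model to an adhesion-frequency curve
#'
#' Binomial maximum likelihood of the small-system adhesion law
#' `p(t) = 1 - exp(-mu_inf (1 - exp(-k_off t)))` over the per-point cycle
#' counts, estimating the plateau mean bound count `mu_inf` and the
#' effective off-rate. The SS effective affinity follows from
#' `K_a = mu_inf N_A A_c / (n_R n_L)`.
#'
#' @param curve An `adhesion_curve` (attributes carry densities and contact
#'   area) with at least 3 contact-time points.
#' @param n_receptors,n_ligands,contact_area Override the generator
#'   attributes when fitting externally produced curves.
#' @return A [fit_result()] with `estimates$eff` an SS 2D
#'   [effective_constants()] and `estimates$mu_inf`; all-zero or all-one
#'   frequency curves are flagged `non_identifiable`.
#' @export
fit_adhesion_curve <- function(curve,
                               n_receptors = attr(curve, "n_receptors"),
                               n_ligands = attr(curve, "n_ligands"),
                               contact_area = attr(curve, "contact_area")) {
  if (nrow(curve) < 3L) stop("need at least 3 contact-time points", call. = FALSE)
  k <- curve$adhered
  m <- curve$cycles
  if (all(k == 0) || all(k == m)) {
    return(fit_result(estimates = list(eff = NULL, mu_inf = NA_real_),
                      converged = FALSE, residual_norm = NA_real_,
                      flags = "non_identifiable"))
  }
  t <- curve$contact_time
  nll <- function(par) {
    mu <- exp(par[1L]) * (1 - exp(-exp(par[2L]) * t))
    p <- pmin(pmax(1 - exp(-mu), 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(k, m, p, log = TRUE))
  }
  p_max <- max(pmin(k / m, 1 - 1e-6))
  mu0 <- max(-log(1 - p_max), 0.05)
  k0 <- 1 / max(t[which.max(k / m >= 0.63 * p_max)], t[1L])
  opt <- stats::optim(c(log(mu0), log(k0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu_inf <- exp(opt$par[1L])
  k_off <- exp(opt$par[2L])
  K_a <- mu_inf * .avogadro * contact_area / (n_receptors * n_ligands)
  fit_result(
    estimates = list(
      eff = effective_constants("SS", "2D", k_on = K_a * k_off,
                                k_off = k_off),
      mu_inf = mu_inf),
    converged = opt$convergence == 0, residual_norm = opt$value)
}
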