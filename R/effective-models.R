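#' Effective-model catalogue
#'
#' The four effective models an assay can impose on the three-step chain:
#' * `PBA` (pre-binding model A, 2D): encounter and orientation lumped into a
#'   single pre-binding species `<RL> = RL* + RL`; describes the thermal
#'   fluctuation assay.
#' * `PBB` (pre-binding model B, 2D or 3D): unbinding and de-orientation
#'   lumped, eliminating the oriented complex `RL`; the 3D variant describes
#'   bulk (solution) FRET.
#' * `FRET` (2D): meta-states `<R> = R + RL*`, `<L> = L + RL*`,
#'   `<C> = RL + C` imposed by what donor/acceptor fluorescence can resolve.
#' * `SS` (single-step, 2D or 3D): only bound (`C`) vs unbound; describes the
#'   adhesion frequency (2D) and SPR (3D) assays.
#' @name effective_models
NULL

.kind_table <- list(
  PBA  = list(dims = "2D",             eq = list(`2D` = 6:8)),
  PBB  = list(dims = c("2D", "3D"),    eq = list(`2D` = 9:11, `3D` = 12:14)),
  FRET = list(dims = "2D",             eq = list(`2D` = 15:17)),
  SS   = list(dims = c("2D", "3D"),    eq = list(`2D` = 18:20, `3D` = 21:23))
)

.check_kind <- function(kind, dimension) {
  kind <- match.arg(kind, names(.kind_table))
  if (!dimension %in% .kind_table[[kind]]$dims) {
    stop(sprintf("effective model %s is not defined in %s", kind, dimension),
         call. = FALSE)
  }
  kind
}

#' Map fundamental constants to the effective constants of one assay model
#'
#' Closed-form quasi-steady-state reductions of the full three-step chain,
#' one row triple (on-rate, off-rate, affinity) per model and dimension:
#' \describe{
#'   \item{PBA (2D)}{`k_on = k+ E/(1+E)` (so `k_on ~ E k+` for `E << 1`),
#'     `k_off = k-`, `K_a = E K_A/(1+E)`. Rotational pre-equilibrium inside
#'     the lumped `<RL>` leaves the oriented fraction `E/(1+E)` available for
#'     binding. The lumped transport step keeps `d+` and reduces the reverse
#'     rate to `d-/(1+E)`.}
#'   \item{PBB (2D/3D)}{`k_on = e+ k+/(e- + k+)`, `k_off = e- k-/(e- + k+)`,
#'     `K_a = E K_A` (dimensionless). The oriented complex is a short-lived
#'     relay between `RL*` and `C`.}
#'   \item{FRET (2D)}{`k_on = K_D e+` (ligand independent; 2D bimolecular
#'     units), `k_off = e-/(1+K_A)`, `K_a = K_D E (1+K_A)`. Diffusion is
#'     pre-equilibrated (`RL* = K_D R L`) and the binding step is
#'     pre-equilibrated inside `<C>` (oriented fraction `1/(1+K_A)`).}
#'   \item{SS (2D/3D)}{`k_on = d+ e+ k+ / Delta`, `k_off = d- e- k- / Delta`
#'     with `Delta = d- e- + d- k+ + e+ k+`, and `K_a = K_D E K_A`. The
#'     on-rate runs from the transport-limited ceiling `d+ e+/(d- + e+)` to
#'     the reaction-limited form `K_D E k+`; the off-rate from `k-` down to
#'     its transport-limited floor.}
#' }
#' Every triple satisfies `K_a = k_on/k_off` exactly.
#'
#' @param params A [fundamental_constants()] object.
#' @param kind One of `"PBA"`, `"PBB"`, `"FRET"`, `"SS"`.
#' @return An `effective_constants` object: list with `kind`, `dimension`,
#'   `k_on`, `k_off`, `K_a`, the equation row ids `eq` (6--23), and for the
#'   pre-binding models the lumped `transport` step constants used by
#'   [simulate_effective()].
#' @export
reduce_to_effective <- function(params, kind = c("PBA", "PBB", "FRET", "SS")) {
  stopifnot(inherits(params, "fundamental_constants"))
  kind <- .check_kind(match.arg(kind), params$dimension)
  aff <- affinities(params)
  transport <- NULL
  if (kind == "PBA") {
    k_on <- params$k_plus * aff$E / (1 + aff$E)
    k_off <- params$k_minus
    transport <- list(on = params$d_plus, off = params$d_minus / (1 + aff$E))
  } else if (kind == "PBB") {
    denom <- params$e_minus + params$k_plus
    if (denom == 0) stop("PBB reduction undefined for e- = k+ = 0", call. = FALSE)
    k_on <- params$e_plus * params$k_plus / denom
    k_off <- params$e_minus * params$k_minus / denom
    transport <- list(on = params$d_plus, off = params$d_minus)
  } else if (kind == "FRET") {
    k_on <- aff$K_D * params$e_plus
    k_off <- params$e_minus / (1 + aff$K_A)
  } else { # SS
    delta <- params$d_minus * params$e_minus +
      params$d_minus * params$k_plus + params$e_plus * params$k_plus
    if (delta == 0) stop("SS reduction undefined: all pathways frozen", call. = FALSE)
    k_on <- params$d_plus * params$e_plus * params$k_plus / delta
    k_off <- params$d_minus * params$e_minus * params$k_minus / delta
  }
  effective_constants(kind, params$dimension, k_on = k_on, k_off = k_off,
                      transport = transport)
}

#' Construct an effective-constants object
#'
#' @param kind,dimension Model tag and dimension (validated against the model
#'   catalogue).
#' @param k_on,k_off Effective on/off rate constants; `K_a` is derived as
#'   their ratio (or supplied, in which case consistency is checked to
#'   relative 1e-12).
#' @param K_a Optional effective affinity.
#' @param transport Optional lumped transport-step constants (pre-binding
#'   models).
#' @return An `effective_constants` object.
#' @export
effective_constants <- function(kind, dimension, k_on, k_off, K_a = NULL,
                                transport = NULL) {
  kind <- .check_kind(kind, dimension)
  if (k_on < 0 || k_off < 0) stop("effective constants must be >= 0", call. = FALSE)
  ratio <- if (k_off > 0) k_on / k_off else Inf
  if (is.null(K_a)) {
    K_a <- ratio
  } else if (is.finite(ratio) && ratio > 0 &&
             abs(K_a - ratio) > 1e-12 * ratio) {
    stop("K_a inconsistent with k_on/k_off", call. = FALSE)
  }
  structure(list(kind = kind, dimension = dimension, k_on = k_on,
                 k_off = k_off, K_a = K_a,
                 eq = .kind_table[[kind]]$eq[[dimension]],
                 transport = transport),
            class = "effective_constants")
}

#' @export
print.effective_constants <- function(x, ...) {
  cat(sprintf("Effective constants [%s, %s] (rows %s)\n", x$kind, x$dimension,
              paste(x$eq, collapse = "-")))
  cat(sprintf("  k_on = %g, k_off = %g s^-1, K_a = %g\n", x$k_on, x$k_off, x$K_a))
  invisible(x)
}

#' Transport- and reaction-limited bounds of the single-step on-rate
#'
#' The SS effective on-rate combines the transport-limited ceiling
#' `TL = d+ e+/(d- + e+)` (binding much faster than transport) and the
#' reaction-limited form `RL = K_D E k+` (binding much slower) harmonically:
#' `1/k_on = 1/TL + 1/RL` exactly. Over a ligand series the on-rate
#' therefore ranges up to whichever bound is smaller, reaching `TL` for fast
#' binders and `RL` for slow ones.
#'
#' @param params A [fundamental_constants()] object.
#' @return List with `transport_limited` and `reaction_limited`.
#' @export
ss_on_rate_bounds <- function(params) {
  aff <- affinities(params)
  list(transport_limited = params$d_plus * params$e_plus /
         (params$d_minus + params$e_plus),
       reaction_limited = aff$K_D * aff$E * params$k_plus)
}

#' Invert an effective-constant triple back to fundamental constants
#'
#' Algebraic inversion of the per-model reduction given the
#' ligand-independent transport and rotation constants. Different assays
#' determine different subsets of `(k+, k-, K_A)`; anything the assayed row
#' does not carry is reported as `NA` with `determined = FALSE`, never
#' guessed:
#' * PBA determines `k- = k_off` exactly and `k+ = k_on (1+E)/E`.
#' * PBB determines `k+ = e- k_on/(e+ - k_on)` (requires `k_on < e+`) and
#'   `k- = k_off (e- + k+)/e-`.
#' * FRET determines only `K_A = e-/k_off - 1`: its on-rate is ligand
#'   independent, so `k+` and `k-` are individually undetermined.
#' * SS determines `k+ = k_on d- e- / (d+ e+ - k_on (d- + e+))` (undetermined
#'   at or beyond the transport limit, where the denominator vanishes) and
#'   `k- = k+ / K_A` with `K_A = K_a/(K_D E)`.
#'
#' @param eff An `effective_constants` object.
#' @param known A [fundamental_constants()] object (or list) supplying the
#'   ligand-independent `d_plus`, `d_minus`, `e_plus`, `e_minus` for the same
#'   dimension.
#' @return A list with `k_plus`, `k_minus`, `K_A` (NA when undetermined) and
#'   a logical vector `determined`.
#' @export
invert_effective <- function(eff, known) {
  stopifnot(inherits(eff, "effective_constants"))
  E <- known$e_plus / known$e_minus
  K_D <- known$d_plus / known$d_minus
  k_plus <- k_minus <- K_A <- NA_real_
  if (eff$kind == "PBA") {
    k_minus <- eff$k_off
    k_plus <- eff$k_on * (1 + E) / E
    K_A <- k_plus / k_minus
  } else if (eff$kind == "PBB") {
    if (eff$k_on < known$e_plus) {
      k_plus <- known$e_minus * eff$k_on / (known$e_plus - eff$k_on)
      k_minus <- eff$k_off * (known$e_minus + k_plus) / known$e_minus
      K_A <- k_plus / k_minus
    }
  } else if (eff$kind == "FRET") {
    if (eff$k_off > 0 && eff$k_off < known$e_minus) {
      K_A <- known$e_minus / eff$k_off - 1
    }
  } else { # SS
    K_A_try <- eff$K_a / (K_D * E)
    den <- known$d_plus * known$e_plus -
      eff$k_on * (known$d_minus + known$e_plus)
    if (den > 0) {
      k_plus <- eff$k_on * known$d_minus * known$e_minus / den
      K_A <- K_A_try
      k_minus <- k_plus / K_A
    }
  }
  list(k_plus = k_plus, k_minus = k_minus, K_A = K_A,
       determined = c(k_plus = !is.na(k_plus), k_minus = !is.na(k_minus),
                      K_A = !is.na(K_A)))
}

#' Project a full-model trajectory onto the observables of an assay model
#'
#' Groups the five species into what the assay can see, preserving total
#' mass: `FRET` reports `<R> = R + RL*`, `<L> = L + RL*`, `<C> = RL + C`;
#' `SS` reports bound `C` against pooled unbound receptor/ligand mass;
#' `PBA` pools `<RL> = RL* + RL`; `PBB` pools the transient oriented complex
#' with the encounter complex (`<RL*> = RL* + RL`).
#'
#' @param traj A `kin_trajectory` (or data frame with the five species
#'   columns and `time`).
#' @param kind Effective model tag.
#' @return Data frame of grouped observables over time.
#' @export
project_trajectory <- function(traj, kind = c("PBA", "PBB", "FRET", "SS")) {
  kind <- match.arg(kind)
  t <- traj$time
  if (kind == "FRET") {
    data.frame(time = t, R = traj$R + traj$RL_star, L = traj$L + traj$RL_star,
               C = traj$RL + traj$C)
  } else if (kind == "SS") {
    inter <- traj$RL_star + traj$RL
    data.frame(time = t, R = traj$R + inter, L = traj$L + inter, C = traj$C)
  } else if (kind == "PBA") {
    data.frame(time = t, R = traj$R, L = traj$L,
               RL = traj$RL_star + traj$RL, C = traj$C)
  } else {
    data.frame(time = t, R = traj$R, L = traj$L,
               RL_star = traj$RL_star + traj$RL, C = traj$C)
  }
}

#' Integrate an effective (reduced) model
#'
#' The reduced ODE systems corresponding to each assay model, run with the
#' same stiff-capable integrator as the full model. `SS` and `FRET` are
#' two-state bimolecular systems in the grouped coordinates; `PBA` and `PBB`
#' retain an explicit pre-binding species fed by the (lumped) transport step
#' carried in `eff$transport`.
#'
#' @param eff An `effective_constants` object (from [reduce_to_effective()]
#'   or [effective_constants()]).
#' @param initial Named non-negative vector in the grouped coordinates
#'   (columns of [project_trajectory()] output, minus `time`).
#' @param times Strictly increasing time grid.
#' @param rtol,atol Integration tolerances.
#' @return Data frame of the grouped state over time.
#' @export
simulate_effective <- function(eff, initial, times, rtol = 1e-10, atol = NULL) {
  stopifnot(inherits(eff, "effective_constants"))
  if (any(initial < 0)) stop("initial grouped state must be non-negative",
                             call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (is.null(atol)) atol <- 1e-12 * max(sum(initial), 1e-30)
  kind <- eff$kind
  if (kind %in% c("SS", "FRET")) {
    y0 <- initial[c("R", "L", "C")]
    deriv <- function(t, y, p) {
      f <- eff$k_on * y[1L] * y[2L] - eff$k_off * y[3L]
      list(c(-f, -f, f))
    }
  } else {
    pre <- if (kind == "PBA") "RL" else "RL_star"
    y0 <- initial[c("R", "L", pre, "C")]
    tr <- eff$transport
    if (is.null(tr)) stop("pre-binding model needs lumped transport constants",
                          call. = FALSE)
    deriv <- function(t, y, p) {
      f_d <- tr$on * y[1L] * y[2L] - tr$off * y[3L]
      f_k <- eff$k_on * y[3L] - eff$k_off * y[4L]
      list(c(-f_d, -f_d, f_d - f_k, f_k))
    }
  }
  out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  traj <- as.data.frame(out)
  names(traj) <- c("time", names(y0))
  traj
}

## fast-step scaling per model kind: which fundamental rates are sent to the
## fast limit to realize the grouping, chosen so the QSS error vanishes as
## the separation factor grows (see the methods vignette).
.fast_steps <- list(
  PBA = c("e_plus", "e_minus"),
  PBB = c("e_minus", "k_plus"),
  FRET = c("d_plus", "d_minus", "k_plus", "k_minus"),
  SS = c("d_plus", "d_minus", "e_plus", "e_minus")
)

## uniform multiplier for the fast set making the relaxation rate of the
## eliminated intermediates exactly s-fold the rate scale of the observable
## slow step; preserves the fast-step affinities (K_D, E, K_A as relevant).
.fast_multiplier <- function(params, kind, s, conc_scale) {
  p <- params
  enc <- p$d_plus * conc_scale # pseudo-first-order encounter rate
  if (kind == "PBA") {
    relax <- p$e_plus + p$e_minus
    slow <- max(p$k_plus, p$k_minus, p$d_minus, enc)
  } else if (kind == "PBB") {
    relax <- p$e_minus + p$k_plus
    slow <- max(p$e_plus, p$k_minus, p$d_minus, enc)
  } else if (kind == "FRET") {
    relax <- min(p$d_minus + enc, p$k_plus + p$k_minus)
    slow <- max(p$e_plus, p$e_minus)
  } else {
    ## the two eliminated intermediates relax in series; the relay lag is the
    ## sum of their residence times
    relax <- 1 / (1 / (p$d_minus + p$e_plus) + 1 / p$e_minus)
    slow <- max(p$k_plus, p$k_minus)
  }
  if (relax <= 0) stop("fast steps are frozen; no reduction limit exists",
                       call. = FALSE)
  s * max(slow, 1e-12) / relax
}

#' Numerically validate an effective reduction
#'
#' The reduction oracle: scales the model's fast steps `s`-fold, integrates
#' the full five-species model, projects it onto the assay observables, runs
#' the effective model built by [reduce_to_effective()] from the scaled
#' constants, and reports the maximum deviation of the bound observable
#' relative to its peak. The deviation must shrink as `s` grows; this guards
#' the closed-form rows against transcription drift.
#'
#' @param params Base [fundamental_constants()].
#' @param kind Effective model tag.
#' @param s Separation factor (>= 10).
#' @param R_total,L_total Conserved totals (all mass initially free).
#' @param times Optional time grid; defaults to 400 points over five
#'   effective off-rate times.
#' @return List with `kind`, `s`, `max_rel_dev`, the effective constants
#'   used and the two bound trajectories.
#' @export
validate_reduction <- function(params, kind = c("PBA", "PBB", "FRET", "SS"),
                               s, R_total = 1, L_total = 1, times = NULL) {
  stopifnot(inherits(params, "fundamental_constants"))
  kind <- .check_kind(match.arg(kind), params$dimension)
  if (s < 10) stop("separation factor s must be >= 10", call. = FALSE)
  m <- .fast_multiplier(params, kind, s, max(R_total, L_total))
  scaled <- params
  for (nm in .fast_steps[[kind]]) scaled[[nm]] <- scaled[[nm]] * m
  eff <- reduce_to_effective(scaled, kind)
  if (is.null(times)) {
    rate <- max(eff$k_off, eff$k_on * max(R_total, L_total), 1e-6)
    times <- seq(0, 5 / rate, length.out = 400L)
  }
  init <- species_state(R = R_total, L = L_total)
  full <- simulate_kinetics(scaled, init, times)
  proj <- project_trajectory(full, kind)
  eff_traj <- simulate_effective(eff, unlist(proj[1L, -1L]), times)
  obs_full <- proj$C
  obs_eff <- eff_traj$C
  scale <- max(obs_full)
  dev <- if (scale > 0) max(abs(obs_eff - obs_full)) / scale else {
    max(abs(obs_eff - obs_full))
  }
  list(kind = kind, s = s, max_rel_dev = dev, effective = eff,
       bound_full = obs_full, bound_effective = obs_eff, times = times)
}
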