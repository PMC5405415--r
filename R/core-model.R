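#' Mass-action time derivatives of the five-species model
#'
#' The coupled ODE system for the three reversible steps
#' `R + L <-> RL* <-> RL <-> C`:
#' \deqn{d[R]/dt = d[L]/dt = -d^+ [R][L] + d^- [RL^*]}
#' \deqn{d[RL^*]/dt = d^+ [R][L] - (d^- + e^+)[RL^*] + e^- [RL]}
#' \deqn{d[RL]/dt = e^+ [RL^*] - (e^- + k^+)[RL] + k^- [C]}
#' \deqn{d[C]/dt = k^+ [RL] - k^- [C]}
#' Mass action forces both conservation laws: the receptor-species derivatives
#' sum to zero, as do the ligand-species derivatives.
#'
#' @param params A [fundamental_constants()] object.
#' @param state A named species vector ([species_state()]); all entries must be
#'   non-negative.
#' @return Named numeric vector of derivatives, same names as `state`.
#' @export
rate_equations <- function(params, state) {
  stopifnot(inherits(params, "fundamental_constants"))
  state <- state[.species_names]
  if (any(is.na(state))) stop("state must name all five species", call. = FALSE)
  if (any(state < 0)) stop("negative concentration in state", call. = FALSE)
  enc <- params$d_plus * state[["R"]] * state[["L"]]
  f_d <- enc - params$d_minus * state[["RL_star"]]
  f_e <- params$e_plus * state[["RL_star"]] - params$e_minus * state[["RL"]]
  f_k <- params$k_plus * state[["RL"]] - params$k_minus * state[["C"]]
  c(R = -f_d, L = -f_d, RL_star = f_d - f_e, RL = f_e - f_k, C = f_k)
}

#' Integrate the full deterministic model
#'
#' Solves the five-species mass-action system with a stiff-capable integrator.
#' Timescale-separation regimes (fast diffusion or rotation against slow
#' binding) are stiff by construction, so `deSolve::lsoda` is used with tight
#' tolerances; the absolute tolerance defaults to `1e-12` times the largest
#' conserved total.
#'
#' @param params A [fundamental_constants()] object.
#' @param initial Initial species vector ([species_state()]).
#' @param times Strictly increasing numeric vector of times (s); the first
#'   entry is the initial time.
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#' @return A `kin_trajectory`: a data frame with columns `time`, `R`, `L`,
#'   `RL_star`, `RL`, `C` and the parameters attached as attribute `params`.
#' @export
simulate_kinetics <- function(params, initial, times,
                              rtol = 1e-10, atol = NULL) {
  stopifnot(inherits(params, "fundamental_constants"))
  initial <- initial[.species_names]
  if (any(is.na(initial)) || any(initial < 0)) {
    stop("initial state must be a non-negative five-species vector",
         call. = FALSE)
  }
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two entries",
         call. = FALSE)
  }
  tot <- conserved_totals(initial)
  if (is.null(atol)) atol <- 1e-12 * max(tot$R_total, tot$L_total, 1e-30)
  deriv <- function(t, y, p) list(rate_equations(params, pmax(y, 0)))
  out <- deSolve::lsoda(y = initial, times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1L] < 0) {
    stop(sprintf(paste0("stiff integration failed (istate = %d) for params: ",
                        "d+=%g d-=%g e+=%g e-=%g k+=%g k-=%g"),
                 attr(out, "istate")[1L], params$d_plus, params$d_minus,
                 params$e_plus, params$e_minus, params$k_plus, params$k_minus),
         call. = FALSE)
  }
  traj <- as.data.frame(out)
  names(traj)[1L] <- "time"
  structure(traj, params = params, class = c("kin_trajectory", "data.frame"))
}

#' Equilibrium state of the full model
#'
#' Closed-form equilibrium from the three detailed-balance relations
#' `RL*/(R L) = K_D`, `RL/RL* = E`, `C/RL = K_A` combined with the two
#' conservation laws. Eliminating the complexes leaves a scalar quadratic in
#' free `R` with a unique non-negative root (equivalently a scalar polynomial
#' in any single species); the root is computed in closed form and the
#' remaining species follow from detailed balance, so conservation is exact to
#' rounding.
#'
#' @param params A [fundamental_constants()] object; all three off-rates must
#'   be strictly positive (a zero off-rate has no finite equilibrium in the
#'   intermediate species).
#' @param R_total,L_total Conserved totals (same units as concentrations).
#' @return A named species vector at equilibrium.
#' @export
equilibrium_state <- function(params, R_total, L_total) {
  stopifnot(inherits(params, "fundamental_constants"))
  if (R_total < 0 || L_total < 0) stop("totals must be >= 0", call. = FALSE)
  if (params$d_minus <= 0 || params$e_minus <= 0 || params$k_minus <= 0) {
    stop("equilibrium requires strictly positive off-rates", call. = FALSE)
  }
  aff <- affinities(params)
  ## total complexed mass = alpha * R * L with alpha = K_D (1 + E + E K_A)
  alpha <- aff$K_D * (1 + aff$E + aff$E * aff$K_A)
  delta <- R_total - L_total
  if (alpha == 0 || R_total == 0 || L_total == 0) {
    R <- R_total
  } else {
    ## alpha R^2 + (1 - alpha delta) R - R_total = 0, take the positive root
    b <- 1 - alpha * delta
    R <- (-b + sqrt(b * b + 4 * alpha * R_total)) / (2 * alpha)
  }
  L <- R - delta
  x <- aff$K_D * R * L
  y <- aff$E * x
  species_state(R = R, L = max(L, 0), RL_star = x, RL = y, C = aff$K_A * y)
}

#' Check conservation along a trajectory
#'
#' @param traj A `kin_trajectory`.
#' @return Maximum relative drift of the receptor and ligand totals.
#' @keywords internal
#' @export
conservation_drift <- function(traj) {
  bound <- traj$RL_star + traj$RL + traj$C
  rt <- traj$R + bound
  lt <- traj$L + bound
  max(abs(rt - rt[1L]) / max(rt[1L], 1e-300),
      abs(lt - lt[1L]) / max(lt[1L], 1e-300))
}
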