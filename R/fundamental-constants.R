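#' Fundamental kinetic constants of the three-step binding model
#'
#' Bundles the six step-level rate constants of the three reversible steps of
#' receptor--ligand association: translational diffusion/encounter
#' (`d_plus`, `d_minus`), rotational orientation (`e_plus`, `e_minus`) and
#' chemical binding (`k_plus`, `k_minus`), together with the dimensionality of
#' the setting. In 3D the diffusion on-rate is a molar on-rate (M^-1 s^-1); in
#' 2D, with both molecules membrane-anchored, its units are um^2 mol^-1 s^-1
#' and concentrations are surface densities (mol um^-2). All other rates are
#' first order (s^-1). The binding constants `k_plus`, `k_minus` are
#' dimension-independent: they describe the chemistry of the docked complex.
#'
#' @param dimension `"2D"` or `"3D"`.
#' @param d_plus,d_minus Diffusion (encounter) on/off rate constants.
#' @param e_plus,e_minus Rotational (orientation) on/off rate constants (s^-1).
#' @param k_plus,k_minus Chemical binding on/off rate constants (s^-1).
#' @return An object of class `fundamental_constants`.
#' @seealso [affinities()] for the derived step affinities.
#' @examples
#' fc <- fundamental_constants("2D", d_plus = 10, d_minus = 8,
#'                             e_plus = 1, e_minus = 25,
#'                             k_plus = 1, k_minus = 0.2)
#' affinities(fc)
#' @export
fundamental_constants <- function(dimension = c("2D", "3D"),
                                  d_plus, d_minus, e_plus, e_minus,
                                  k_plus, k_minus) {
  dimension <- match.arg(dimension)
  rates <- c(d_plus = d_plus, d_minus = d_minus,
             e_plus = e_plus, e_minus = e_minus,
             k_plus = k_plus, k_minus = k_minus)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all six fundamental rate constants must be finite and >= 0",
         call. = FALSE)
  }
  structure(c(as.list(rates), list(dimension = dimension)),
            class = "fundamental_constants")
}

#' @export
print.fundamental_constants <- function(x, ...) {
  cat(sprintf("Fundamental kinetic constants (%s)\n", x$dimension))
  cat(sprintf("  diffusion : d+ = %g%s, d- = %g s^-1\n", x$d_plus,
              if (x$dimension == "3D") " M^-1 s^-1" else " um^2 mol^-1 s^-1",
              x$d_minus))
  cat(sprintf("  rotation  : e+ = %g s^-1, e- = %g s^-1\n", x$e_plus, x$e_minus))
  cat(sprintf("  binding   : k+ = %g s^-1, k- = %g s^-1\n", x$k_plus, x$k_minus))
  aff <- affinities(x)
  cat(sprintf("  affinities: K_D = %g, E = %g, K_A = %g\n",
              aff$K_D, aff$E, aff$K_A))
  invisible(x)
}

#' Step affinities derived from fundamental constants
#'
#' The three step-wise affinity constants: diffusion `K_D = d+/d-` (M^-1 in
#' 3D, um^2 mol^-1 in 2D), rotation `E = e+/e-` (dimensionless) and binding
#' `K_A = k+/k-` (dimensionless).
#'
#' @param params A [fundamental_constants()] object.
#' @return A list with components `K_D`, `E`, `K_A`.
#' @export
affinities <- function(params) {
  stopifnot(inherits(params, "fundamental_constants"))
  list(K_D = params$d_plus / params$d_minus,
       E = params$e_plus / params$e_minus,
       K_A = params$k_plus / params$k_minus)
}

#' Species state of the five-species binding model
#'
#' A named, validated concentration vector over the species of the three-step
#' reaction chain: free receptor `R`, free ligand `L`, encounter complex
#' `RL_star` (within reaction distance, not oriented), oriented complex `RL`,
#' and bound complex `C`.
#'
#' @param R,L,RL_star,RL,C Non-negative concentrations (M in 3D,
#'   mol um^-2 in 2D).
#' @return A named numeric vector of length 5.
#' @export
species_state <- function(R, L, RL_star = 0, RL = 0, C = 0) {
  s <- c(R = R, L = L, RL_star = RL_star, RL = RL, C = C)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("species concentrations must be finite and non-negative",
         call. = FALSE)
  }
  s
}

.species_names <- c("R", "L", "RL_star", "RL", "C")

#' Conserved totals of a species state
#'
#' Receptor mass `R + RL_star + RL + C` and ligand mass `L + RL_star + RL + C`
#' are invariants of the reaction chain.
#'
#' @param state A named species vector as returned by [species_state()].
#' @return A list with `R_total` and `L_total`.
#' @export
conserved_totals <- function(state) {
  bound <- state[["RL_star"]] + state[["RL"]] + state[["C"]]
  list(R_total = state[["R"]] + bound, L_total = state[["L"]] + bound)
}
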