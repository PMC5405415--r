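#' Geometry parameters for ligand-independent transport constants
#'
#' Physical geometry of the encounter step and of the SPR flow cell. Lengths
#' are in micrometres, the diffusion coefficient in um^2/s. The contact area
#' is tied to the encounter radius: `A_c = pi a^2`.
#'
#' @param D Translational diffusion coefficient (um^2 s^-1).
#' @param a Encounter radius (um), of the order of the receptor diameter.
#' @param b Mean inter-receptor distance on the membrane (um); must exceed `a`.
#' @param v Flow rate through the SPR cell (um^3 s^-1), optional.
#' @param h Flow-cell height (um), optional.
#' @param L_cell Distance from the flow-cell inlet to the sampling area (um),
#'   optional.
#' @return A `geometry_params` object; `A_c` is derived, never supplied.
#' @export
geometry_params <- function(D, a, b, v = NULL, h = NULL, L_cell = NULL) {
  if (!is.finite(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  if (!is.finite(a) || a <= 0) stop("encounter radius a must be > 0", call. = FALSE)
  if (!is.finite(b) || b <= a) {
    stop("mean inter-receptor distance b must exceed the encounter radius a",
         call. = FALSE)
  }
  for (nm in c("v", "h", "L_cell")) {
    val <- get(nm)
    if (!is.null(val) && (!is.finite(val) || val <= 0)) {
      stop(sprintf("%s must be > 0 when supplied", nm), call. = FALSE)
    }
  }
  structure(list(D = D, a = a, b = b, A_c = pi * a^2,
                 v = v, h = h, L_cell = L_cell, N_A = .avogadro),
            class = "geometry_params")
}

#' 2D diffusion-limited encounter on-rate
#'
#' Classical two-dimensional diffusion-limited capture rate for a trap of
#' radius `a` collecting ligand diffusing within a mean catchment radius `b`:
#' per molecular pair the rate is `2 pi D / ln(b/a)` (um^2 s^-1), converted
#' to mole-based surface-concentration units by Avogadro's number:
#' \deqn{d^+ = \frac{2\pi D N_A}{\ln(b/a)} \quad [\mu m^2\, mol^{-1} s^{-1}].}
#' The logarithmic dependence on `b/a` is the signature of 2D diffusion:
#' the rate diverges as `b -> a` (encounter immediate) and is linear in `D`.
#' No binding constant enters: the result is ligand independent.
#'
#' @param geom A [geometry_params()] object.
#' @return Diffusion on-rate `d_plus` in um^2 mol^-1 s^-1.
#' @export
diffusion_on_rate_2d <- function(geom) {
  stopifnot(inherits(geom, "geometry_params"))
  2 * pi * geom$D * geom$N_A / log(geom$b / geom$a)
}

#' SPR flow-cell transport on-rate
#'
#' Laminar-flow mass-transport coefficient of a rectangular flow cell
#' (Leveque-type cube-root law): the analyte flux to the sensor surface
#' scales as
#' \deqn{k_M = 1.282 \left(\frac{v\, D^2}{h\, L}\right)^{1/3},}
#' increasing with flow rate `v` and diffusivity `D` and decreasing with cell
#' height `h` and inlet distance `L`. The coefficient is converted to a molar
#' on-rate (M^-1 s^-1) by the supplied per-site capture cross-section:
#' `d_plus = k_M * site_conversion`, where the default conversion uses the
#' encounter area `pi a^2` and Avogadro's number with um/litre bookkeeping
#' (1 litre = 1e15 um^3). Ligand independent by construction.
#'
#' @param geom A [geometry_params()] object with `v`, `h`, `L_cell` set.
#' @param site_conversion Conversion from the transport coefficient (um s^-1)
#'   to a molar on-rate; defaults to `pi a^2 * N_A / 1e15` (um^2 per site,
#'   litres to um^3).
#' @return SPR transport-limited on-rate `d_plus` in M^-1 s^-1.
#' @export
spr_transport_rate <- function(geom, site_conversion = NULL) {
  stopifnot(inherits(geom, "geometry_params"))
  if (is.null(geom$v) || is.null(geom$h) || is.null(geom$L_cell)) {
    stop("flow-cell geometry (v, h, L_cell) is required", call. = FALSE)
  }
  k_M <- 1.282 * (geom$v * geom$D^2 / (geom$h * geom$L_cell))^(1 / 3)
  if (is.null(site_conversion)) {
    site_conversion <- pi * geom$a^2 * geom$N_A / 1e15
  }
  k_M * site_conversion
}

#' Default rotational equilibrium constant
#'
#' The rotational affinity `E = e+/e-` is ligand independent. In 2D the
#' membrane constrains the rotational degrees of freedom and the accepted
#' estimate is `E_2D = 0.04`. No comparable 3D value is established: in 3D
#' the constant must be user-configured or estimated from matched assays
#' ([estimate_rotational_constants()]); requesting it unconfigured returns
#' `NA` with an `unset` attribute rather than a silent guess.
#'
#' @param dimension `"2D"` or `"3D"`.
#' @param override Optional user-configured value taking precedence.
#' @return The rotational equilibrium constant, or `NA` (attribute
#'   `unset = TRUE`) for an unconfigured 3D request.
#' @export
rotational_equilibrium_default <- function(dimension = c("2D", "3D"),
                                           override = NULL) {
  dimension <- match.arg(dimension)
  if (!is.null(override)) {
    if (!is.finite(override) || override <= 0) {
      stop("override for E must be a positive number", call. = FALSE)
    }
    return(override)
  }
  if (dimension == "2D") return(0.04)
  structure(NA_real_, unset = TRUE)
}
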