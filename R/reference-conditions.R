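#' Reference study conditions for the synthetic assays
#'
#' The package's canonical parameter sets for emulating each assay class,
#' chosen once to represent a realistic membrane/flow-cell setting and used
#' by the examples, the test-suite and the acceptance analysis:
#' \describe{
#'   \item{TF}{thermal fluctuation: one bond at a time, `k- = 0.2` s^-1
#'     (the AF ligand), 10^4 lifetimes per experiment.}
#'   \item{AF}{adhesion frequency: contact area 3 um^2 holding 400 receptors
#'     and 400 ligands (~130 molecules/um^2); per-receptor encounter rate
#'     0.15 s^-1 with encounter break-up `d- = 24` s^-1, so the encounter
#'     pool stays sparse (<1% occupancy) as the single-step analysis
#'     assumes; rotation `e+ = 3`, `e- = 75` s^-1 (the standard 2D
#'     rotational affinity E = 0.04); ligand `k+ = 2`, `k- = 0.2` s^-1;
#'     contact times 2, 5, 10, 20 s at 2000 cycles per point.}
#'   \item{SPR}{3D single step: `d+ = 1e7` M^-1 s^-1, `d- = 1e3` s^-1,
#'     `e+ = 100`, `e- = 1e3` s^-1, ligand `k+ = 50`, `k- = 0.05` s^-1
#'     (reaction-limited, so the binding constants are identifiable);
#'     analyte at twice the effective dissociation constant, 120 s
#'     association / 240 s dissociation, 500 samples, R_max 100 RU, 1 RU
#'     Gaussian noise (1% of R_max).}
#'   \item{FRET}{2D meta-state imaging of the AF membrane system at dilute
#'     surface densities.}
#' }
#'
#' @param assay One of `"TF"`, `"AF"`, `"SPR"`, `"FRET"`.
#' @return A list with `params` ([fundamental_constants()]), `shared` (the
#'   ligand-independent constants as a plain list) and the per-assay
#'   settings.
#' @export
reference_conditions <- function(assay = c("AF", "SPR", "TF", "FRET")) {
  assay <- match.arg(assay)
  if (assay %in% c("AF", "TF", "FRET")) {
    contact_area <- 3
    n_receptors <- 400L
    n_ligands <- 400L
    d_plus <- 0.15 * .avogadro * contact_area / n_ligands
    shared <- list(dimension = "2D", d_plus = d_plus, d_minus = 24,
                   e_plus = 3, e_minus = 75)
    params <- fundamental_constants("2D", d_plus, 24, 3, 75,
                                    k_plus = 2, k_minus = 0.2)
    if (assay == "TF") {
      return(list(params = params, shared = shared, n = 10000L))
    }
    if (assay == "FRET") {
      conc <- n_receptors / (.avogadro * contact_area)
      return(list(params = params, shared = shared,
                  initial = species_state(R = conc, L = conc),
                  times = seq(0, 25, length.out = 201L)))
    }
    return(list(params = params, shared = shared,
                n_receptors = n_receptors, n_ligands = n_ligands,
                contact_area = contact_area,
                contact_times = c(2, 5, 10, 20), cycles = 2000L))
  }
  shared <- list(dimension = "3D", d_plus = 1e7, d_minus = 1e3,
                 e_plus = 100, e_minus = 1e3)
  params <- fundamental_constants("3D", 1e7, 1e3, 100, 1e3,
                                  k_plus = 50, k_minus = 0.05)
  eff <- reduce_to_effective(params, "SS")
  list(params = params, shared = shared, conc = 2 / eff$K_a,
       t_assoc = 120, t_dissoc = 240, R_max = 100, noise_sd = 1,
       n_points = 500L)
}
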