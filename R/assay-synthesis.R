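#' Sample single-bond lifetimes (thermal fluctuation assay)
#'
#' The thermal fluctuation assay watches one pre-formed bond at a time; under
#' the pre-binding model A its dissociation is a single exponential with rate
#' equal to the fundamental unbinding constant (`k_off = k-`). Lifetimes are
#' therefore i.i.d. exponential draws with rate `k_off_eff`.
#'
#' @param k_off_eff Effective off-rate (s^-1), > 0.
#' @param n Number of observed bond lifetimes (>= 1).
#' @param seed Integer seed (reproducibility contract).
#' @return A `lifetime_sample`: list with `durations`, `k_off_eff`, `seed`.
#' @export
sample_tf_lifetimes <- function(k_off_eff, n, seed) {
  if (!is.finite(k_off_eff) || k_off_eff <= 0) {
    stop("k_off_eff must be > 0", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  structure(list(durations = stats::rexp(n, rate = k_off_eff),
                 k_off_eff = k_off_eff, seed = seed),
            class = "lifetime_sample")
}

#' Synthesize an adhesion-frequency curve (micropipette assay)
#'
#' Generates adhesion frequencies mechanistically: each test cycle places
#' `n_receptors` and `n_ligands` free molecules in the contact area, runs the
#' exact stochastic three-step chain for the contact duration, and scores
#' adhesion when at least one bound complex `C` is present at contact end.
#' The per-point frequency is the fraction of adhering cycles, so the noise
#' is exactly binomial. At long contact times and low occupancy the expected
#' plateau is `1 - exp(-<n_C>)` with `<n_C>` the equilibrium mean bound
#' count (Poisson small-number statistics).
#'
#' @param params 2D [fundamental_constants()].
#' @param n_receptors,n_ligands Molecule counts in the contact area.
#' @param contact_area Contact area `A_c` (um^2).
#' @param contact_times Vector of contact durations (s).
#' @param cycles Test cycles per contact time (>= 1).
#' @param seed Integer seed.
#' @return An `adhesion_curve`: data frame of `contact_time`, `frequency`,
#'   `adhered`, `cycles` with the generating settings as attributes.
#' @export
synthesize_af_curve <- function(params, n_receptors, n_ligands, contact_area,
                                contact_times, cycles, seed) {
  stopifnot(inherits(params, "fundamental_constants"))
  if (params$dimension != "2D") stop("the adhesion frequency assay is 2D",
                                     call. = FALSE)
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (contact_area <= 0 || n_receptors <= 0 || n_ligands <= 0) {
    stop("densities and contact area must be positive", call. = FALSE)
  }
  rates <- c(params$d_plus, params$d_minus, params$e_plus, params$e_minus,
             params$k_plus, params$k_minus)
  set.seed(seed)
  adhered <- cpp_af_cycles(rates, .avogadro * contact_area,
                           as.integer(n_receptors), as.integer(n_ligands),
                           as.numeric(contact_times), as.integer(cycles))
  structure(data.frame(contact_time = as.numeric(contact_times),
                       frequency = adhered / cycles,
                       adhered = adhered, cycles = cycles),
            params = params, n_receptors = n_receptors,
            n_ligands = n_ligands, contact_area = contact_area, seed = seed,
            class = c("adhesion_curve", "data.frame"))
}

#' Expected adhesion frequency under the single-step model
#'
#' Small-system closed form: bound complexes form as an immigration-death
#' process, so the bound count at contact time `t` is Poisson with mean
#' `mu(t) = mu_inf (1 - exp(-k_off t))` and the adhesion probability is
#' `1 - exp(-mu(t))`. The plateau `mu_inf = n_R n_L K_a / (N_A A_c)` follows
#' from the SS effective affinity.
#'
#' @param eff SS 2D `effective_constants`.
#' @param n_receptors,n_ligands,contact_area As in [synthesize_af_curve()].
#' @param contact_times Contact durations (s).
#' @return Vector of expected adhesion frequencies.
#' @export
af_expected_frequency <- function(eff, n_receptors, n_ligands, contact_area,
                                  contact_times) {
  stopifnot(inherits(eff, "effective_constants"), eff$kind == "SS")
  mu_inf <- n_receptors * n_ligands * eff$K_a / (.avogadro * contact_area)
  1 - exp(-mu_inf * (1 - exp(-eff$k_off * contact_times)))
}

#' Synthesize an SPR sensorgram (single-step 3D model)
#'
#' Two-phase 1:1 interaction kinetics: during association at analyte
#' concentration `conc` the response follows
#' `R(t) = R_eq (1 - exp(-(k_on conc + k_off) t))` with
#' `R_eq = R_max K_a conc / (1 + K_a conc)`; during dissociation the signal
#' decays as `exp(-k_off (t - t_assoc))`. Additive Gaussian noise.
#'
#' @param eff SS 3D `effective_constants` (`k_on` in M^-1 s^-1).
#' @param conc Analyte concentration during association (M), >= 0.
#' @param t_assoc,t_dissoc Durations (s) of the two phases.
#' @param R_max Saturation response (arbitrary response units).
#' @param n_points Number of samples over the whole sensorgram.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed Integer seed.
#' @return A `sensorgram`: data frame of `time`, `signal`, `conc` (the
#'   analyte schedule) with generating settings as attributes.
#' @export
synthesize_sensorgram <- function(eff, conc, t_assoc, t_dissoc, R_max,
                                  n_points = 500L, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(eff, "effective_constants"), eff$kind == "SS")
  if (eff$dimension != "3D") stop("SPR sensorgrams use the 3D SS model",
                                  call. = FALSE)
  if (conc < 0) stop("analyte concentration must be >= 0", call. = FALSE)
  if (t_assoc <= 0 || t_dissoc <= 0) {
    stop("both association and dissociation phases are required", call. = FALSE)
  }
  times <- seq(0, t_assoc + t_dissoc, length.out = n_points)
  clean <- spr_signal(times, eff$k_on, eff$k_off, conc, t_assoc, R_max)
  set.seed(seed)
  signal <- clean + stats::rnorm(n_points, sd = noise_sd)
  structure(data.frame(time = times, signal = signal,
                       conc = ifelse(times <= t_assoc, conc, 0)),
            eff = eff, R_max = R_max, t_assoc = t_assoc, noise_sd = noise_sd,
            seed = seed, clean = clean,
            class = c("sensorgram", "data.frame"))
}

#' Noiseless two-phase 1:1 sensorgram signal
#'
#' @param times Time grid spanning both phases.
#' @param k_on,k_off Effective 3D constants.
#' @param conc Association-phase analyte concentration (M).
#' @param t_assoc Association duration (s).
#' @param R_max Saturation response.
#' @return Numeric signal vector.
#' @keywords internal
#' @export
spr_signal <- function(times, k_on, k_off, conc, t_assoc, R_max) {
  kobs <- k_on * conc + k_off
  R_eq <- if (kobs > 0) R_max * k_on * conc / kobs else 0
  assoc <- R_eq * (1 - exp(-kobs * pmin(times, t_assoc)))
  B1 <- R_eq * (1 - exp(-kobs * t_assoc))
  ifelse(times <= t_assoc, assoc, B1 * exp(-k_off * (times - t_assoc)))
}

#' Synthesize a FRET trace from the full 2D model
#'
#' Integrates the five-species model, projects it onto the FRET meta-states
#' and reports a donor channel proportional to `<L> = L + RL*` (free or
#' merely encountered ligand) and an acceptor channel proportional to
#' `<C> = RL + C` (oriented or bound), with additive Gaussian noise. With
#' zero noise the channels equal the projected trajectory scaled by the
#' gains.
#'
#' @param params 2D [fundamental_constants()].
#' @param initial Initial species vector.
#' @param times Time grid.
#' @param gains Named vector `c(donor = , acceptor = )` of channel gains.
#' @param noise_sd Gaussian noise sd (signal units).
#' @param seed Integer seed.
#' @return A `fret_trace`: data frame of `time`, `donor`, `acceptor` with
#'   the noiseless projection as attribute `clean`.
#' @export
synthesize_fret_trace <- function(params, initial, times,
                                  gains = c(donor = 1, acceptor = 1),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "fundamental_constants"))
  if (params$dimension != "2D") stop("single-molecule FRET traces are 2D",
                                     call. = FALSE)
  proj <- project_trajectory(simulate_kinetics(params, initial, times), "FRET")
  clean_donor <- gains[["donor"]] * proj$L
  clean_acceptor <- gains[["acceptor"]] * proj$C
  set.seed(seed)
  n <- length(times)
  structure(data.frame(time = proj$time,
                       donor = clean_donor + stats::rnorm(n, sd = noise_sd),
                       acceptor = clean_acceptor + stats::rnorm(n, sd = noise_sd)),
            clean = data.frame(time = proj$time, donor = clean_donor,
                               acceptor = clean_acceptor),
            gains = gains, noise_sd = noise_sd, seed = seed, params = params,
            class = c("fret_trace", "data.frame"))
}

#' Generate a synthetic ligand panel
#'
#' A panel of named ligands emulating an altered-peptide-ligand series: the
#' binding on-rate spans `fold_k_plus` (default 1000-fold) and the off-rate
#' `fold_k_minus` (default 10-fold), both increasing with ligand potency, as
#' observed for 2D effective constants; potency (the proxy 1/EC50) spans
#' `fold_potency`. Values are log-spaced; with `jitter_sd = 0` the requested
#' fold-ranges are met exactly and the potency rank order equals the binding
#' affinity rank order (the default coupling). `jitter_sd` adds log10-normal
#' scatter for randomized panels. The implied binding affinity `K_A = k+/k-`
#' then spans `fold_k_plus/fold_k_minus`. Ligand names follow the
#' ovalbumin-variant convention; all parameter values are synthetic.
#'
#' @param n Panel size (>= 2).
#' @param fold_k_plus,fold_k_minus Fold-ranges imposed on the binding on/off
#'   rates (> 0).
#' @param k_plus_max,k_minus_max Values for the most potent ligand (s^-1).
#' @param fold_potency Fold-range of the potency proxy 1/EC50.
#' @param jitter_sd Log10 scatter added to the rate constants (0 = noiseless).
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @param names Ligand names, least to most potent.
#' @return A `ligand_panel`: data frame with `name`, `k_plus`, `k_minus`,
#'   `K_A`, `potency`.
#' @export
make_ligand_panel <- function(n = 6L, fold_k_plus = 1e3, fold_k_minus = 10,
                              k_plus_max = 1, k_minus_max = 0.5,
                              fold_potency = 1e3, jitter_sd = 0, seed = 1L,
                              names = NULL) {
  if (n < 2) stop("a panel needs at least 2 ligands", call. = FALSE)
  if (fold_k_plus <= 0 || fold_k_minus <= 0 || fold_potency <= 0) {
    stop("fold-ranges must be positive", call. = FALSE)
  }
  if (is.null(names)) {
    base <- c("R4", "V-OVA", "E1", "G4", "A2", "OVA")
    names <- if (n <= 6L) utils::tail(base, n) else {
      c(paste0("APL", seq_len(n - 6L)), base)
    }
  }
  grid <- seq(0, 1, length.out = n) # 0 = least potent
  lk_plus <- log10(k_plus_max) - (1 - grid) * log10(fold_k_plus)
  lk_minus <- log10(k_minus_max) - (1 - grid) * log10(fold_k_minus)
  if (jitter_sd > 0) {
    set.seed(seed)
    lk_plus <- lk_plus + stats::rnorm(n, sd = jitter_sd)
    lk_minus <- lk_minus + stats::rnorm(n, sd = jitter_sd)
  }
  potency <- 10^(seq(0, log10(fold_potency), length.out = n))
  k_plus <- 10^lk_plus
  k_minus <- 10^lk_minus
  structure(data.frame(name = names, k_plus = k_plus, k_minus = k_minus,
                       K_A = k_plus / k_minus, potency = potency,
                       stringsAsFactors = FALSE),
            seed = seed, jitter_sd = jitter_sd,
            class = c("ligand_panel", "data.frame"))
}

#' Fundamental constants for one panel ligand
#'
#' Combines a ligand's binding constants with the panel-wide
#' ligand-independent transport and rotation constants.
#'
#' @param panel A `ligand_panel`.
#' @param i Ligand row index.
#' @param shared A [fundamental_constants()] object (or list with
#'   `dimension`, `d_plus`, `d_minus`, `e_plus`, `e_minus`) carrying the
#'   ligand-independent constants.
#' @return A [fundamental_constants()] object for ligand `i`.
#' @export
panel_params <- function(panel, i, shared) {
  fundamental_constants(shared$dimension,
                        d_plus = shared$d_plus, d_minus = shared$d_minus,
                        e_plus = shared$e_plus, e_minus = shared$e_minus,
                        k_plus = panel$k_plus[i], k_minus = panel$k_minus[i])
}
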