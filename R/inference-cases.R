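#' Ordinary least-squares trend line in log-log space
#'
#' Regresses `log10(constant)` on `log10(potency)` across a ligand panel.
#' This orientation makes the framework's algebra transparent: when an
#' effective constant is a fundamental constant times a ligand-independent
#' factor, the two trend lines have identical slopes and differ only in
#' intercept, the intercept difference being the log10 of that factor (the
#' horizontal shift between the lines in a potency-vs-constant plot).
#'
#' @param values Positive per-ligand constants.
#' @param potency Per-ligand potency proxy 1/EC50.
#' @param constant Label of the constant.
#' @param assay Assay/model tag.
#' @return A `trend_line`: list with `constant`, `assay`, `slope`,
#'   `intercept`, `n`.
#' @export
fit_trend_line <- function(values, potency, constant = "", assay = "") {
  if (length(values) < 2L) stop("trend fitting needs >= 2 ligands", call. = FALSE)
  if (any(values <= 0) || any(potency <= 0)) {
    stop("trend lines are fitted in log space: values must be positive",
         call. = FALSE)
  }
  x <- log10(potency)
  if (stats::sd(x) == 0) stop("degenerate panel: potency has zero variance",
                              call. = FALSE)
  y <- log10(values)
  cf <- stats::coef(stats::lm(y ~ x))
  structure(list(constant = constant, assay = assay,
                 slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 n = length(values)),
            class = "trend_line")
}

#' Per-ligand effective constants across a panel
#'
#' Applies [reduce_to_effective()] ligand by ligand, or its limiting
#' (transport- or reaction-limited) single-step forms. The limiting forms
#' are the log-decomposable expressions behind the trend-line algebra: in
#' the reaction-limited SS regime `k_on = K_D E k+`, `k_off = k-`,
#' `K_a = K_D E K_A`; in the transport-limited regime
#' `k_on = d+ e+/(d- + e+)` (ligand independent) and `k_off = k_on/K_a`.
#'
#' @param panel A `ligand_panel`.
#' @param shared Ligand-independent constants (list with `dimension`,
#'   `d_plus`, `d_minus`, `e_plus`, `e_minus`).
#' @param kind Effective model tag.
#' @param regime `"exact"` (the full closed forms), `"reaction"` or
#'   `"transport"` (SS limiting forms).
#' @return Data frame with `name`, `k_on`, `k_off`, `K_a`.
#' @export
effective_panel <- function(panel, shared, kind = "SS",
                            regime = c("exact", "reaction", "transport")) {
  regime <- match.arg(regime)
  K_D <- shared$d_plus / shared$d_minus
  E <- shared$e_plus / shared$e_minus
  if (regime == "exact" || kind != "SS") {
    rows <- lapply(seq_len(nrow(panel)), function(i) {
      eff <- reduce_to_effective(panel_params(panel, i, shared), kind)
      c(k_on = eff$k_on, k_off = eff$k_off, K_a = eff$K_a)
    })
    out <- as.data.frame(do.call(rbind, rows))
  } else if (regime == "reaction") {
    out <- data.frame(k_on = K_D * E * panel$k_plus,
                      k_off = panel$k_minus,
                      K_a = K_D * E * panel$K_A)
  } else {
    kon_T <- shared$d_plus * shared$e_plus / (shared$d_minus + shared$e_plus)
    K_a <- K_D * E * panel$K_A
    out <- data.frame(k_on = rep(kon_T, nrow(panel)),
                      k_off = kon_T / K_a, K_a = K_a)
  }
  cbind(name = panel$name, out)
}

#' Case 1: which pre-binding model describes the thermal fluctuation assay
#'
#' The TF and AF assays report the same off-rate across ligands. Under the
#' pre-binding model A this requires the binding on-rate to be much slower
#' than the rotational off-rate (`k+ << e-`), so that the single-step AF
#' off-rate reduces to `k-`, the PBA off-rate. Under the pre-binding model B
#' the TF off-rate is `e- k-/(e- + k+)`: matching the common value `k-`
#' needs `k+ << e-` for every ligand while the model's premise (multiple
#' binding/unbinding events before de-orientation) needs `e- < k-`; one
#' ligand-independent `e-` must therefore satisfy
#' `max(k+)/threshold <= e- <= min(k-)` across the whole panel, which fails
#' as soon as any ligand has `K_A` of order the threshold or larger. The
#' verdict reports both conditions.
#'
#' @param params 2D [fundamental_constants()] supplying `e_minus` (and the
#'   other ligand-independent constants).
#' @param panel A `ligand_panel` for the ligand-dependence test.
#' @param threshold Operational meaning of "much less than" as a ratio
#'   (default 1e-2).
#' @return A `case_verdict` list: per-condition ratios, booleans, and a
#'   conclusion string.
#' @export
case1_tf_model_selection <- function(params, panel, threshold = 1e-2) {
  stopifnot(inherits(params, "fundamental_constants"))
  ratio_pba <- max(panel$k_plus) / params$e_minus
  pba_ok <- ratio_pba <= threshold
  pbb_lower <- max(panel$k_plus) / threshold # e- must be at least this
  pbb_upper <- min(panel$k_minus)            # and below this
  pbb_ok <- pbb_lower <= pbb_upper
  conclusion <- if (pba_ok && !pbb_ok) {
    "TF assay is consistent with the pre-binding model A (PBA); PBB rejected: no ligand-independent e- can match the common AF/TF off-rate across the panel"
  } else if (pba_ok) {
    "both pre-binding conditions satisfiable; PBA adopted by default"
  } else {
    "PBA condition violated: binding on-rate not slow against rotational off-rate"
  }
  structure(list(case = 1L,
                 pba = list(ratio = ratio_pba, threshold = threshold,
                            admissible = pba_ok,
                            origin = "reduce_to_effective(PBA/SS)"),
                 pbb = list(e_minus_lower = pbb_lower,
                            e_minus_upper = pbb_upper,
                            admissible = pbb_ok,
                            origin = "reduce_to_effective(PBB/SS)"),
                 conclusion = conclusion),
            class = "case_verdict")
}

#' Case 2: trend lines of AF (2D) and SPR (3D) single-step constants
#'
#' Log-decomposes the single-step effective constants across a ligand panel
#' and fits potency trend lines for both the effective and the fundamental
#' constants. In the reaction-limited 2D regime (AF): identical slopes, the
#' off-rate lines coincide (zero shift), and the on-rate/affinity lines are
#' shifted by `log10(K_D E)`. In the transport-limited 3D regime (SPR): the
#' effective on-rate is ligand independent (zero slope) and the off-rate
#' slope is the negative of the affinity slope.
#'
#' @param panel A `ligand_panel`.
#' @param shared Ligand-independent constants for the assay's dimension.
#' @param assay `"AF"` or `"SPR"`.
#' @return List of `trend_line`s for the effective (`k_on`, `k_off`, `K_a`)
#'   and fundamental (`k_plus`, `k_minus`, `K_A`) constants, plus the
#'   x-shifts `shift` (effective minus fundamental intercept, per constant).
#' @export
case2_trend_lines <- function(panel, shared, assay = c("AF", "SPR")) {
  assay <- match.arg(assay)
  regime <- if (assay == "AF") "reaction" else "transport"
  eff <- effective_panel(panel, shared, "SS", regime)
  trends <- list(
    k_on = fit_trend_line(eff$k_on, panel$potency, "k_on", assay),
    k_off = fit_trend_line(eff$k_off, panel$potency, "k_off", assay),
    K_a = fit_trend_line(eff$K_a, panel$potency, "K_a", assay),
    k_plus = fit_trend_line(panel$k_plus, panel$potency, "k_plus", "fundamental"),
    k_minus = fit_trend_line(panel$k_minus, panel$potency, "k_minus", "fundamental"),
    K_A = fit_trend_line(panel$K_A, panel$potency, "K_A", "fundamental"))
  shift <- c(k_on = trends$k_on$intercept - trends$k_plus$intercept,
             k_off = trends$k_off$intercept - trends$k_minus$intercept,
             K_a = trends$K_a$intercept - trends$K_A$intercept)
  c(trends, list(shift = shift, assay = assay, regime = regime))
}

#' Cases 3 and 4: FRET predictions against SPR and AF
#'
#' Computes per-ligand 2D FRET and (reaction-limited) AF effective constants
#' and the structural contrasts between them: the FRET on-rate is ligand
#' independent; the FRET off-rate `e-/(1+K_A)` falls with binding affinity
#' while the AF off-rate tracks `k-`, so ligands with equal intrinsic
#' off-rates can disagree between the assays; and the effective affinities
#' differ per ligand by exactly `(K_A + 1)/K_A`, converging for strong
#' binders.
#'
#' @param panel A `ligand_panel`.
#' @param shared Ligand-independent 2D constants.
#' @return List with `fret` and `af` per-ligand constants, trend lines,
#'   per-ligand `affinity_ratio`, and a `case_verdict`.
#' @export
case3_case4_fret_predictions <- function(panel, shared) {
  fret <- effective_panel(panel, shared, "FRET", "exact")
  af <- effective_panel(panel, shared, "SS", "reaction")
  ratio <- fret$K_a / af$K_a
  fret_kon_independent <- stats::sd(log10(fret$k_on)) == 0
  trends <- list(
    fret_k_off = fit_trend_line(fret$k_off, panel$potency, "k_off", "FRET2D"),
    af_k_off = fit_trend_line(af$k_off, panel$potency, "k_off", "AF"),
    fret_K_a = fit_trend_line(fret$K_a, panel$potency, "K_a", "FRET2D"),
    af_K_a = fit_trend_line(af$K_a, panel$potency, "K_a", "AF"))
  verdict <- structure(list(
    case = c(3L, 4L),
    fret_kon_ligand_independent = fret_kon_independent,
    fret_koff_tracks_inverse_affinity = trends$fret_k_off$slope < 0 ||
      stats::sd(log10(panel$K_A)) == 0,
    affinity_ratio_matches = max(abs(ratio * panel$K_A / (panel$K_A + 1) - 1)),
    origin = "reduce_to_effective(FRET/SS)"), class = "case_verdict")
  list(fret = fret, af = af, affinity_ratio = ratio, trends = trends,
       verdict = verdict)
}

#' Case 5: rotational equilibrium constants from matched assays
#'
#' The 2D FRET and AF effective affinities differ per ligand only through
#' the `(K_A + 1)` vs `K_A` factor, so the pair determines the binding
#' affinity, `K_A = K_AF/(K_FRET - K_AF)`, and with the ligand-independent
#' 2D diffusion affinity known, the 2D rotational constant
#' `E_2D = K_FRET/(K_D (1 + K_A))`. The difference `K_FRET - K_AF` loses
#' precision for strong binders, so the route is flagged invalid when the
#' panel's median `K_A` is not small (>= 1). The 3D rotational constant
#' follows from the bulk-FRET (3D) affinity, `E_3D = K_a(bulk FRET)/K_A`,
#' and, when the 3D diffusion affinity is supplied, is cross-checked against
#' the SPR affinity `K_a(SPR) = K_D3 E_3D K_A`.
#'
#' @param fret2d,af Lists of per-ligand `effective_constants` (matched
#'   ligand order) from the 2D FRET and AF assays.
#' @param fret3d,spr Optional matched lists from bulk FRET (3D) and SPR.
#' @param kd2d Ligand-independent 2D diffusion affinity `K_D = d+/d-`.
#' @param kd3d Optional 3D diffusion affinity (for the SPR cross-check).
#' @param ka_threshold Validity bound on the panel median `K_A` (default 1).
#' @return List with `E2D`, `E3D` (NA when not estimable), per-ligand `K_A`,
#'   `valid` flags and, with a single ligand, a `no_consistency_check` flag.
#' @export
estimate_rotational_constants <- function(fret2d, af, fret3d = NULL,
                                          spr = NULL, kd2d, kd3d = NULL,
                                          ka_threshold = 1) {
  n <- length(fret2d)
  if (length(af) != n || (!is.null(fret3d) && length(fret3d) != n) ||
      (!is.null(spr) && length(spr) != n)) {
    stop("assay lists must cover the same matched ligand set", call. = FALSE)
  }
  K_fret <- vapply(fret2d, function(e) e$K_a, numeric(1))
  K_af <- vapply(af, function(e) e$K_a, numeric(1))
  diff <- K_fret - K_af
  K_A <- ifelse(diff > 0, K_af / diff, NA_real_)
  E2D_per <- K_fret / (kd2d * (1 + K_A))
  flags <- character()
  valid_e2d <- all(is.finite(K_A)) && stats::median(K_A) < ka_threshold
  if (!valid_e2d) flags <- c(flags, "K_A_not_small")
  if (n < 2L) flags <- c(flags, "no_consistency_check")
  E3D <- NA_real_
  E3D_per <- NULL
  spr_consistency <- NULL
  if (!is.null(fret3d)) {
    E3D_per <- vapply(fret3d, function(e) e$K_a, numeric(1)) / K_A
    E3D <- stats::median(E3D_per)
  }
  if (!is.null(spr) && !is.null(kd3d) && is.finite(E3D)) {
    K_spr <- vapply(spr, function(e) e$K_a, numeric(1))
    spr_consistency <- K_spr / (kd3d * E3D * K_A)
  }
  list(E2D = stats::median(E2D_per), E2D_per_ligand = E2D_per,
       E3D = E3D, E3D_per_ligand = E3D_per, K_A = K_A,
       valid = list(E2D = valid_e2d && n >= 1,
                    E3D = !is.null(fret3d) && all(is.finite(K_A))),
       spr_consistency = spr_consistency, flags = flags)
}
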