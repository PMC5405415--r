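#' Exact stochastic simulation of the three-step binding chain
#'
#' Event-driven (Gillespie direct method) counterpart of the deterministic
#' five-species model, in molecule counts. The bimolecular encounter
#' propensity is `d_plus * nR * nL / (N_A * volume)`, consistent with the
#' deterministic term `d_plus [R][L]` when counts are converted to
#' concentrations by `n / (N_A * volume)`; all other reactions are first
#' order in counts. `volume` is a reaction volume (3D, in the volume unit the
#' concentration units of `params` imply, e.g. litres for molar constants) or
#' a contact area (2D, um^2 for mol um^-2 concentrations).
#'
#' @param params A [fundamental_constants()] object.
#' @param counts Named integer vector of initial molecule counts
#'   (`R`, `L`, `RL_star`, `RL`, `C`); missing species default to 0.
#' @param volume Reaction volume (3D) or contact area (2D); must be positive
#'   whenever the bimolecular step is active (`d_plus > 0` with both free
#'   species present).
#' @param t_max End time (s).
#' @param seed Integer seed; required, so that the same seed reproduces the
#'   identical event list.
#' @param times Optional numeric vector of times at which to record the state.
#' @param record_events If `TRUE` (default) return the full event list.
#' @param max_events Abort guard on the number of reaction events (0 = none).
#' @return A list with `events` (data frame of `time` and `reaction`, the
#'   1-based reaction index in the order encounter, encounter break-up,
#'   orientation, de-orientation, binding, unbinding), `states` (data frame of
#'   counts at `times`, if requested), `final` counts and `n_events`.
#' @export
stochastic_simulate <- function(params, counts, volume, t_max, seed,
                                times = NULL, record_events = TRUE,
                                max_events = 0L) {
  stopifnot(inherits(params, "fundamental_constants"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible stochastic simulation",
         call. = FALSE)
  }
  n0 <- stats::setNames(integer(5L), .species_names)
  if (!is.null(names(counts))) {
    bad <- setdiff(names(counts), .species_names)
    if (length(bad)) stop("unknown species in counts: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    n0[names(counts)] <- as.integer(counts)
  } else {
    n0[seq_along(counts)] <- as.integer(counts)
  }
  if (any(n0 < 0)) stop("counts must be >= 0", call. = FALSE)
  bimol_active <- params$d_plus > 0 && n0[["R"]] > 0 && n0[["L"]] > 0
  if (bimol_active && volume <= 0) {
    stop("volume (or contact area) must be > 0 when the bimolecular step is active",
         call. = FALSE)
  }
  volNA <- .avogadro * max(volume, 0)
  rates <- c(params$d_plus, params$d_minus, params$e_plus, params$e_minus,
             params$k_plus, params$k_minus)
  rec_times <- if (is.null(times)) numeric(0) else as.numeric(times)
  set.seed(seed)
  res <- cpp_gillespie(rates, volNA, unname(n0), t_max, rec_times,
                       record_events, as.integer(max_events))
  out <- list(
    events = if (record_events) {
      data.frame(time = res$event_times, reaction = res$event_types)
    } else NULL,
    states = if (length(rec_times)) {
      st <- as.data.frame(res$states)
      names(st) <- .species_names
      cbind(time = rec_times, st)
    } else NULL,
    final = stats::setNames(res$final, .species_names),
    n_events = res$n_events,
    seed = seed)
  out
}

## Avogadro constant (mol^-1), used to convert counts to mole-based
## concentrations.
.avogadro <- 6.02214076e23
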