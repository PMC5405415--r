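#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a model/assay run: the fundamental
#' rate block, totals, optional geometry, ligand panel and per-assay
#' settings, a global seed and an output directory. Validation is
#' schema-based, rejects unknown keys, and reports *all* violations at once.
#' Documented defaults are applied for optional blocks (totals 1/1 in the
#' model's concentration units, seed 1).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

.config_keys <- c("dimension", "rates", "totals", "geometry", "panel",
                  "assays", "seed", "output_dir", "tolerances")
.rate_keys <- c("d_plus", "d_minus", "e_plus", "e_minus", "k_plus", "k_minus")

#' Validate a configuration list
#'
#' @param cfg A list as parsed from YAML.
#' @return A `run_config` with defaults applied, or an error naming every
#'   schema violation found.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$dimension)) {
    errs <- c(errs, "missing required block: dimension")
  } else if (!cfg$dimension %in% c("2D", "3D")) {
    errs <- c(errs, "dimension must be '2D' or '3D'")
  }
  if (is.null(cfg$rates)) {
    errs <- c(errs, "missing required block: rates")
  } else {
    missing_rates <- setdiff(.rate_keys, names(cfg$rates))
    if (length(missing_rates)) {
      errs <- c(errs, paste0("rates block missing key(s): ",
                             paste(missing_rates, collapse = ", ")))
    }
    for (nm in intersect(.rate_keys, names(cfg$rates))) {
      v <- cfg$rates[[nm]]
      if (!is.numeric(v) || !is.finite(v) || v < 0) {
        errs <- c(errs, paste0("rates$", nm, " must be a finite number >= 0"))
      }
    }
    extra <- setdiff(names(cfg$rates), .rate_keys)
    if (length(extra)) {
      errs <- c(errs, paste0("unknown rates key(s): ",
                             paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(cfg$totals)) {
    for (nm in c("R_total", "L_total")) {
      v <- cfg$totals[[nm]]
      if (!is.null(v) && (!is.numeric(v) || v < 0)) {
        errs <- c(errs, paste0("totals$", nm, " must be >= 0"))
      }
    }
  }
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) ||
                             cfg$seed != round(cfg$seed))) {
    errs <- c(errs, "seed must be an integer")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$totals <- utils::modifyList(list(R_total = 1, L_total = 1),
                                  cfg$totals %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "."
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration back to YAML
#'
#' `load_config(dump_config(cfg, path))` is idempotent.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_params <- function(cfg) {
  fundamental_constants(cfg$dimension,
                        d_plus = cfg$rates$d_plus, d_minus = cfg$rates$d_minus,
                        e_plus = cfg$rates$e_plus, e_minus = cfg$rates$e_minus,
                        k_plus = cfg$rates$k_plus, k_minus = cfg$rates$k_minus)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a delimited table with a provenance header
#'
#' Comma-separated body with a header row, preceded by '#'-prefixed comment
#' lines recording the package version, seed and configuration hash so every
#' artifact is auditable against its inputs.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed used to produce `df`.
#' @param cfg Optional `run_config` (hashed into the header).
#' @param extra Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_readout <- function(df, path, seed = NA, cfg = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("kinetrans"))
  writeLines(sprintf("# kinetrans %s", ver), con)
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(cfg)) writeLines(sprintf("# config_hash: %s", config_hash(cfg)), con)
  for (nm in names(extra)) writeLines(sprintf("# %s: %s", nm, extra[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a delimited readout file
#'
#' Inverts [write_readout()], skipping '#'-prefixed provenance lines.
#'
#' @param path File path.
#' @return Data frame; parse failures report the offending line number.
#' @export
read_readout <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) stop("no table body in ", path, call. = FALSE)
  out <- tryCatch(
    utils::read.csv(text = paste(lines[body], collapse = "\n")),
    error = function(e) stop(sprintf("corrupted readout %s near line %d: %s",
                                     path, body[1L], conditionMessage(e)),
                             call. = FALSE))
  out
}

seed_for <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Run a pipeline command from a configuration
#'
#' Thin orchestration layer behind the command-line interface. Every output
#' carries a provenance header (version, seed, config hash); identical
#' configuration and seed reproduce byte-identical numeric outputs.
#'
#' Commands: `simulate` (full-model trajectory, or the stochastic event list
#' with `stochastic: true` in `assays$simulate`), `reduce` (table of the
#' effective constants of all applicable models, with their equation row
#' ids), `validate-reduction` (QSS discrepancy report over separation
#' factors), `transport` (derived ligand-independent constants), `synthesize`
#' (per-assay synthetic readouts), `fit` (round-trip fits of the synthesized
#' readouts), `cases` (the case-analysis verdict report) and `trends`
#' (trend-line table).
#'
#' @param cfg A `run_config` from [load_config()].
#' @param command One of the commands above.
#' @param out_dir Output directory; defaults to the configured one.
#' @return Character vector of paths written, invisibly.
#' @export
run_pipeline <- function(cfg, command = c("simulate", "reduce",
                                          "validate-reduction", "transport",
                                          "synthesize", "fit", "cases",
                                          "trends"),
                         out_dir = cfg$output_dir) {
  stopifnot(inherits(cfg, "run_config"))
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  seed <- cfg$seed
  paths <- character()
  emit <- function(df, name, extra = NULL) {
    p <- file.path(out_dir, name)
    write_readout(df, p, seed = seed, cfg = cfg, extra = extra)
    paths <<- c(paths, p)
  }
  shared <- c(cfg$rates[c("d_plus", "d_minus", "e_plus", "e_minus")],
              list(dimension = cfg$dimension))

  if (command == "simulate") {
    sim_cfg <- cfg$assays$simulate %||% list()
    t_end <- sim_cfg$t_end %||% 10
    n_t <- sim_cfg$n_times %||% 201L
    times <- seq(0, t_end, length.out = n_t)
    init <- species_state(R = cfg$totals$R_total, L = cfg$totals$L_total)
    if (isTRUE(sim_cfg$stochastic)) {
      counts <- c(R = sim_cfg$n_receptors %||% 100L,
                  L = sim_cfg$n_ligands %||% 100L)
      res <- stochastic_simulate(params, counts,
                                 volume = sim_cfg$volume %||% 1,
                                 t_max = t_end, seed = seed, times = times)
      emit(res$states, "trajectory_stochastic.csv",
           c(assay = "stochastic-simulate"))
      emit(res$events, "events.csv", c(assay = "stochastic-simulate"))
    } else {
      traj <- simulate_kinetics(params, init, times)
      emit(as.data.frame(traj), "trajectory.csv", c(assay = "simulate"))
    }
  } else if (command == "reduce") {
    kinds <- if (cfg$dimension == "2D") c("PBA", "PBB", "FRET", "SS") else
      c("PBB", "SS")
    rows <- lapply(kinds, function(k) {
      eff <- reduce_to_effective(params, k)
      data.frame(model = k, dimension = eff$dimension,
                 eq_rows = paste(eff$eq, collapse = "-"),
                 k_on = eff$k_on, k_off = eff$k_off, K_a = eff$K_a)
    })
    emit(do.call(rbind, rows), "effective_constants.csv")
  } else if (command == "validate-reduction") {
    kinds <- if (cfg$dimension == "2D") c("PBA", "PBB", "FRET", "SS") else
      c("PBB", "SS")
    s_grid <- cfg$tolerances$separation_factors %||% c(10, 100, 1000)
    rows <- do.call(rbind, lapply(kinds, function(k) {
      devs <- vapply(s_grid, function(s) {
        validate_reduction(params, k, s, cfg$totals$R_total,
                           cfg$totals$L_total)$max_rel_dev
      }, numeric(1))
      data.frame(model = k, s = s_grid, max_rel_dev = devs)
    }))
    emit(rows, "reduction_report.csv")
  } else if (command == "transport") {
    g <- cfg$geometry
    if (is.null(g)) stop("transport command needs a geometry block", call. = FALSE)
    geom <- geometry_params(D = g$D, a = g$a, b = g$b, v = g$v, h = g$h,
                            L_cell = g$L_cell)
    rows <- data.frame(
      constant = c("d_plus_2d", "A_c", "E_2D"),
      value = c(diffusion_on_rate_2d(geom), geom$A_c,
                rotational_equilibrium_default("2D", cfg$rates$E_2D)),
      units = c("um^2 mol^-1 s^-1", "um^2", "-"))
    if (!is.null(g$v)) {
      rows <- rbind(rows, data.frame(constant = "d_plus_spr",
                                     value = spr_transport_rate(geom),
                                     units = "M^-1 s^-1"))
    }
    emit(rows, "transport_constants.csv")
  } else if (command == "synthesize" || command == "fit") {
    a <- cfg$assays %||% list()
    tf <- a$tf %||% list(n = 1000L)
    eff_pba <- reduce_to_effective(params, if (cfg$dimension == "2D") "PBA" else "PBB")
    lt <- sample_tf_lifetimes(eff_pba$k_off, tf$n %||% 1000L, seed_for(seed, 1L))
    emit(data.frame(duration = lt$durations), "tf_lifetimes.csv",
         c(assay = "TF", k_off_eff = lt$k_off_eff))
    if (cfg$dimension == "2D") {
      af <- a$af %||% list()
      curve <- synthesize_af_curve(
        params, af$n_receptors %||% 25L, af$n_ligands %||% 25L,
        af$contact_area %||% 3, af$contact_times %||% c(2, 5, 10, 20),
        af$cycles %||% 200L, seed_for(seed, 2L))
      emit(as.data.frame(curve), "af_curve.csv", c(assay = "AF"))
    }
    if (command == "fit") {
      fit1 <- fit_lifetimes(lt)
      rows <- data.frame(assay = "TF", constant = "k_off",
                         estimate = fit1$estimates$k_off,
                         se = fit1$se[["k_off"]])
      if (cfg$dimension == "2D") {
        fit2 <- fit_adhesion_curve(curve)
        if (!"non_identifiable" %in% fit2$flags) {
          rows <- rbind(rows,
                        data.frame(assay = "AF",
                                   constant = c("k_on", "k_off", "K_a"),
                                   estimate = c(fit2$estimates$eff$k_on,
                                                fit2$estimates$eff$k_off,
                                                fit2$estimates$eff$K_a),
                                   se = NA))
        }
      }
      emit(rows, "fits.csv")
    }
  } else if (command == "cases") {
    p <- cfg$panel %||% list()
    panel <- make_ligand_panel(n = p$n %||% 6L,
                               fold_k_plus = p$fold_k_plus %||% 1e3,
                               fold_k_minus = p$fold_k_minus %||% 10,
                               k_plus_max = p$k_plus_max %||% 1,
                               k_minus_max = p$k_minus_max %||% 0.5,
                               jitter_sd = p$jitter_sd %||% 0,
                               seed = seed_for(seed, 3L))
    v1 <- case1_tf_model_selection(params, panel)
    c34 <- case3_case4_fret_predictions(panel, shared)
    rows <- data.frame(
      case = c("1", "1", "3", "4"),
      condition = c("PBA: max(k+)/e- below threshold",
                    "PBB: single e- feasible across panel",
                    "FRET2D k_on ligand independent",
                    "FRET/AF affinity ratio = (K_A+1)/K_A"),
      outcome = c(v1$pba$admissible, v1$pbb$admissible,
                  c34$verdict$fret_kon_ligand_independent,
                  c34$verdict$affinity_ratio_matches < 1e-8),
      quantity = c(v1$pba$ratio, v1$pbb$e_minus_lower / max(v1$pbb$e_minus_upper, 1e-300),
                   stats::sd(log10(c34$fret$k_on)),
                   c34$verdict$affinity_ratio_matches))
    emit(rows, "case_verdicts.csv", c(conclusion = v1$conclusion))
  } else if (command == "trends") {
    p <- cfg$panel %||% list()
    panel <- make_ligand_panel(n = p$n %||% 6L,
                               fold_k_plus = p$fold_k_plus %||% 1e3,
                               fold_k_minus = p$fold_k_minus %||% 10,
                               k_plus_max = p$k_plus_max %||% 1,
                               k_minus_max = p$k_minus_max %||% 0.5,
                               jitter_sd = p$jitter_sd %||% 0,
                               seed = seed_for(seed, 3L))
    rows <- do.call(rbind, lapply(c("AF", "SPR"), function(assay) {
      tr <- case2_trend_lines(panel, shared, assay)
      do.call(rbind, lapply(c("k_on", "k_off", "K_a",
                              "k_plus", "k_minus", "K_A"), function(nm) {
        data.frame(assay = assay, constant = nm, slope = tr[[nm]]$slope,
                   intercept = tr[[nm]]$intercept)
      }))
    }))
    emit(rows, "trend_lines.csv")
  }
  invisible(paths)
}
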