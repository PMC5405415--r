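test_that("thermal-fluctuation lifetimes follow the generating exponential law", {
  lt <- sample_tf_lifetimes(2, 1e4, seed = 21L)
  expect_equal(mean(lt$durations), 0.5, tolerance = 3 * 0.5 / sqrt(1e4) / 0.5)
  ks <- suppressWarnings(stats::ks.test(lt$durations, "pexp", 2))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(1e4)) # 5% critical value
  expect_identical(lt$durations,
                   sample_tf_lifetimes(2, 1e4, seed = 21L)$durations)
  expect_error(sample_tf_lifetimes(2, 0, seed = 1), "n must be")
  expect_error(sample_tf_lifetimes(0, 10, seed = 1), "k_off_eff")
})

test_that("adhesion frequencies are binomial fractions with the expected plateau", {
  cond <- reference_conditions("AF")
  tt <- c(2, 30) # one kinetic point, one near-plateau point
  freqs <- vapply(1:8, function(s) {
    synthesize_af_curve(cond$params, cond$n_receptors, cond$n_ligands,
                        cond$contact_area, tt, 500L, seed = s)$frequency
  }, numeric(2))
  # expectation monotone in contact time, seed by seed on average
  expect_gt(mean(freqs[2, ]), mean(freqs[1, ]))
  # plateau: Poisson count statistics at the full-model equilibrium occupancy
  conc <- cond$n_receptors / (6.02214076e23 * cond$contact_area)
  eq <- equilibrium_state(cond$params, conc, conc)
  mu_eq <- eq[["C"]] * 6.02214076e23 * cond$contact_area
  p_plateau <- 1 - exp(-mu_eq)
  pooled <- mean(freqs[2, ])
  se <- sqrt(p_plateau * (1 - p_plateau) / (8 * 500))
  expect_lt(abs(pooled - p_plateau), 4 * se + 0.01)
})

test_that("no binding chemistry means no adhesion", {
  cond <- reference_conditions("AF")
  p0 <- fundamental_constants("2D", cond$params$d_plus, cond$params$d_minus,
                              cond$params$e_plus, cond$params$e_minus,
                              k_plus = 0, k_minus = 0.2)
  curve <- synthesize_af_curve(p0, 50, 50, cond$contact_area, c(1, 5), 200L,
                               seed = 3L)
  expect_equal(curve$frequency, c(0, 0))
  expect_error(synthesize_af_curve(cond$params, 50, 50, cond$contact_area,
                                   c(1, 5), 0L, seed = 1), "cycles")
})

test_that("sensorgram phases follow the two-phase 1:1 closed form", {
  cond <- reference_conditions("SPR")
  eff <- reduce_to_effective(cond$params, "SS")
  sg <- synthesize_sensorgram(eff, cond$conc, cond$t_assoc, cond$t_dissoc,
                              cond$R_max, n_points = 400L, noise_sd = 0,
                              seed = 1L)
  # dissociation-phase log slope equals -k_off
  dis <- sg[sg$time > cond$t_assoc + 1, ]
  slope <- stats::coef(stats::lm(log(signal) ~ time, data = dis))[[2L]]
  expect_equal(slope, -eff$k_off, tolerance = 1e-6)
  # association plateau is the Langmuir isotherm
  plateau <- cond$R_max * eff$K_a * cond$conc / (1 + eff$K_a * cond$conc)
  long <- synthesize_sensorgram(eff, cond$conc, 2000, 10, cond$R_max,
                                n_points = 300L, noise_sd = 0, seed = 1L)
  expect_equal(max(long$signal), plateau, tolerance = 1e-6)
  # no analyte, no signal
  flat <- synthesize_sensorgram(eff, 0, 10, 10, 100, n_points = 50L,
                                noise_sd = 0, seed = 1L)
  expect_equal(flat$signal, rep(0, 50L))
})

test_that("FRET channels equal the projected trajectory when noiseless", {
  cond <- reference_conditions("FRET")
  tr <- synthesize_fret_trace(cond$params, cond$initial, cond$times,
                              noise_sd = 0, seed = 5L)
  proj <- project_trajectory(
    simulate_kinetics(cond$params, cond$initial, cond$times), "FRET")
  expect_equal(tr$donor, proj$L, tolerance = 1e-12)
  expect_equal(tr$acceptor, proj$C, tolerance = 1e-12)
  # acceptor channel equilibrates at the oriented-plus-bound occupancy
  eq <- equilibrium_state(cond$params, conserved_totals(cond$initial)$R_total,
                          conserved_totals(cond$initial)$L_total)
  expect_equal(tr$acceptor[length(cond$times)], eq[["RL"]] + eq[["C"]],
               tolerance = 1e-5)
  # seeded reproducibility with noise
  a <- synthesize_fret_trace(cond$params, cond$initial, cond$times,
                             noise_sd = 0.1, seed = 6L)
  b <- synthesize_fret_trace(cond$params, cond$initial, cond$times,
                             noise_sd = 0.1, seed = 6L)
  expect_identical(a$donor, b$donor)
})

test_that("ligand panels impose the requested fold-ranges exactly", {
  panel <- make_ligand_panel(n = 6)
  expect_equal(max(panel$k_plus) / min(panel$k_plus), 1e3, tolerance = 1e-12)
  expect_equal(max(panel$k_minus) / min(panel$k_minus), 10, tolerance = 1e-12)
  expect_equal(max(panel$potency) / min(panel$potency), 1e3, tolerance = 1e-12)
  # default coupling: potency rank order equals binding-affinity rank order
  expect_equal(order(panel$potency), order(panel$K_A))
  two <- make_ligand_panel(n = 2, fold_k_plus = 100, k_plus_max = 5)
  expect_equal(two$k_plus, c(0.05, 5), tolerance = 1e-12)
  expect_error(make_ligand_panel(n = 1), "at least 2")
  expect_error(make_ligand_panel(n = 4, fold_k_plus = -1), "positive")
  # jittered panels keep their seed-reproducibility
  j1 <- make_ligand_panel(n = 6, jitter_sd = 0.1, seed = 4L)
  j2 <- make_ligand_panel(n = 6, jitter_sd = 0.1, seed = 4L)
  expect_identical(j1$k_plus, j2$k_plus)
})
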