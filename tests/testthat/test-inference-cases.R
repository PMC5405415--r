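shared_2d <- reference_conditions("AF")$shared
shared_3d <- reference_conditions("SPR")$shared
kd_2d <- shared_2d$d_plus / shared_2d$d_minus
E_2d <- shared_2d$e_plus / shared_2d$e_minus

test_that("TF model selection adopts PBA and rejects PBB on a wide panel", {
  # binding on-rates well below the rotational off-rate across the panel
  panel <- make_ligand_panel(n = 6, k_plus_max = 0.5, k_minus_max = 0.5)
  params <- panel_params(panel, 6, shared_2d)
  v <- case1_tf_model_selection(params, panel)
  expect_true(v$pba$admissible)
  # PBB would need one ligand-independent e- below every k- yet far above
  # every k+: impossible once some ligand binds faster than others unbind
  expect_false(v$pbb$admissible)
  expect_match(v$conclusion, "PBA")
  # violated separation is reported, not hidden
  fast <- make_ligand_panel(n = 6, k_plus_max = shared_2d$e_minus,
                            k_minus_max = 0.5)
  v2 <- case1_tf_model_selection(panel_params(fast, 6, shared_2d), fast)
  expect_false(v2$pba$admissible)
  expect_equal(v$pba$ratio, 0.5 / shared_2d$e_minus)
})

test_that("AF trend lines: effective and fundamental slopes match exactly", {
  panel <- make_ligand_panel(n = 6)
  tr <- case2_trend_lines(panel, shared_2d, "AF")
  expect_equal(tr$k_on$slope, tr$k_plus$slope, tolerance = 1e-10)
  expect_equal(tr$k_off$slope, tr$k_minus$slope, tolerance = 1e-10)
  expect_equal(tr$K_a$slope, tr$K_A$slope, tolerance = 1e-10)
  # the off-rate line is unshifted; on-rate and affinity lines shift by the
  # log of the ligand-independent factor K_D * E
  expect_equal(tr$shift[["k_off"]], 0, tolerance = 1e-10)
  expect_equal(tr$shift[["k_on"]], log10(kd_2d * E_2d), tolerance = 1e-10)
  expect_equal(tr$shift[["K_a"]], log10(kd_2d * E_2d), tolerance = 1e-10)
})

test_that("AF effective constants span the same log-ranges as the fundamental ones", {
  panel <- make_ligand_panel(n = 6)
  eff <- effective_panel(panel, shared_2d, "SS", "reaction")
  lr <- function(x) diff(range(log10(x)))
  expect_equal(lr(eff$k_on), lr(panel$k_plus), tolerance = 1e-10)
  expect_equal(lr(eff$k_off), lr(panel$k_minus), tolerance = 1e-10)
  expect_equal(lr(eff$K_a), lr(panel$K_A), tolerance = 1e-10)
})

test_that("SPR trend lines: flat on-rate, off-rate mirroring the affinity", {
  panel <- make_ligand_panel(n = 6)
  tr <- case2_trend_lines(panel, shared_3d, "SPR")
  expect_lt(abs(tr$k_on$slope), 1e-6)
  expect_equal(tr$k_off$slope, -tr$K_a$slope, tolerance = 1e-10)
  expect_error(case2_trend_lines(
    make_ligand_panel(n = 3, fold_potency = 1), shared_3d, "SPR"),
    "degenerate")
})

test_that("FRET contrasts: ligand-independent on-rate, affinity ratio (K_A+1)/K_A", {
  panel <- make_ligand_panel(n = 6)
  res <- case3_case4_fret_predictions(panel, shared_2d)
  expect_true(res$verdict$fret_kon_ligand_independent)
  expect_lt(res$verdict$affinity_ratio_matches, 1e-10)
  expect_equal(res$affinity_ratio, (panel$K_A + 1) / panel$K_A,
               tolerance = 1e-10)
  # equal intrinsic off-rates but different affinities: AF off-rates agree,
  # FRET off-rates spread
  flat <- make_ligand_panel(n = 4, fold_k_minus = 1, fold_k_plus = 100)
  res2 <- case3_case4_fret_predictions(flat, shared_2d)
  expect_equal(diff(range(res2$af$k_off)), 0, tolerance = 1e-12)
  expect_gt(diff(range(res2$fret$k_off)) / min(res2$fret$k_off), 1)
  # strong binders: the two effective affinities converge
  strong <- make_ligand_panel(n = 3, k_plus_max = 500, k_minus_max = 0.05)
  res3 <- case3_case4_fret_predictions(strong, shared_2d)
  expect_equal(res3$affinity_ratio[3], 1, tolerance = 1e-3)
})

test_that("matched FRET/AF affinities recover the rotational constants", {
  panel <- make_ligand_panel(n = 6, k_plus_max = 1, k_minus_max = 5) # K_A << 1
  fret2d <- panel_effective_list(panel, shared_2d, "FRET")
  af <- panel_effective_list(panel, shared_2d, "SS")
  fret3d <- panel_effective_list(panel, shared_3d, "PBB")
  est <- estimate_rotational_constants(fret2d, af, fret3d, kd2d = kd_2d)
  expect_equal(est$E2D, E_2d, tolerance = 1e-6)
  expect_equal(est$E3D, shared_3d$e_plus / shared_3d$e_minus,
               tolerance = 1e-6)
  expect_true(est$valid$E2D)
  expect_equal(est$K_A, panel$K_A, tolerance = 1e-8)
})

test_that("the E2D route is flagged invalid for strong-binder panels", {
  panel <- make_ligand_panel(n = 6, k_plus_max = 50, k_minus_max = 0.5)
  expect_true(all(panel$K_A >= 1))
  est <- estimate_rotational_constants(
    panel_effective_list(panel, shared_2d, "FRET"),
    panel_effective_list(panel, shared_2d, "SS"), kd2d = kd_2d)
  expect_false(est$valid$E2D)
  expect_true("K_A_not_small" %in% est$flags)
})

test_that("single-ligand and mismatched inputs are flagged or rejected", {
  panel <- make_ligand_panel(n = 2, k_plus_max = 0.5, k_minus_max = 5)
  f1 <- panel_effective_list(panel[1, , drop = FALSE], shared_2d, "FRET")
  a1 <- panel_effective_list(panel[1, , drop = FALSE], shared_2d, "SS")
  est <- estimate_rotational_constants(f1, a1, kd2d = kd_2d)
  expect_true("no_consistency_check" %in% est$flags)
  expect_equal(est$E2D, E_2d, tolerance = 1e-6)
  expect_error(estimate_rotational_constants(
    f1, panel_effective_list(panel, shared_2d, "SS"), kd2d = kd_2d),
    "matched")
})
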