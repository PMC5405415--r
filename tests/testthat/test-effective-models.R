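test_that("every effective triple satisfies K_a = k_on/k_off and >= 0", {
  for (seed in 1:15) {
    for (kind in c("PBA", "PBB", "FRET", "SS")) {
      p <- draw_fundamental(seed, dilute = needs_dilution(kind))
      eff <- reduce_to_effective(p, kind)
      expect_equal(eff$K_a, eff$k_on / eff$k_off, tolerance = 1e-12)
      expect_true(all(c(eff$k_on, eff$k_off, eff$K_a) >= 0))
    }
  }
})

test_that("PBA off-rate equals the fundamental unbinding constant exactly", {
  for (seed in 1:15) {
    p <- draw_fundamental(seed)
    expect_identical(reduce_to_effective(p, "PBA")$k_off, p$k_minus)
  }
})

test_that("PBA on-rate carries the oriented fraction E/(1+E)", {
  p <- fundamental_constants("2D", 1, 1, e_plus = 0.04, e_minus = 1,
                             k_plus = 1, k_minus = 0.5)
  eff <- reduce_to_effective(p, "PBA")
  expect_equal(eff$k_on, 0.04 / 1.04, tolerance = 1e-12)
  # E << 1: within 4% of the first-order form E * k+
  expect_lt(abs(eff$k_on - 0.04) / 0.04, 0.04)
})

test_that("no productive binding means zero effective on-rate", {
  p <- fundamental_constants("2D", 2, 1, 1, 1, k_plus = 0, k_minus = 0.5)
  expect_equal(reduce_to_effective(p, "SS")$k_on, 0)
  expect_equal(reduce_to_effective(p, "PBA")$k_on, 0)
})

test_that("model kinds are tied to their dimensions", {
  p3 <- draw_fundamental(1, dimension = "3D")
  expect_error(reduce_to_effective(p3, "PBA"), "not defined in 3D")
  expect_error(reduce_to_effective(p3, "FRET"), "not defined in 3D")
  expect_equal(reduce_to_effective(p3, "SS")$eq, 21:23)
  expect_equal(reduce_to_effective(p3, "PBB")$eq, 12:14)
  p2 <- draw_fundamental(1)
  expect_equal(reduce_to_effective(p2, "SS")$eq, 18:20)
})

test_that("SS on-rate combines its transport and reaction bounds harmonically", {
  for (seed in 1:15) {
    p <- draw_fundamental(seed, dilute = TRUE)
    eff <- reduce_to_effective(p, "SS")
    b <- ss_on_rate_bounds(p)
    expect_equal(1 / eff$k_on,
                 1 / b$transport_limited + 1 / b$reaction_limited,
                 tolerance = 1e-12)
    expect_lte(eff$k_on, min(b$transport_limited, b$reaction_limited))
  }
  # each bound is attained in its limiting regime
  base <- draw_fundamental(2, dilute = TRUE)
  fast <- fundamental_constants("2D", base$d_plus, base$d_minus, base$e_plus,
                                base$e_minus, k_plus = 1e8, k_minus = 1)
  expect_equal(reduce_to_effective(fast, "SS")$k_on,
               ss_on_rate_bounds(fast)$transport_limited, tolerance = 1e-6)
  slow <- fundamental_constants("2D", base$d_plus, base$d_minus, base$e_plus,
                                base$e_minus, k_plus = 1e-8, k_minus = 1)
  expect_equal(reduce_to_effective(slow, "SS")$k_on,
               ss_on_rate_bounds(slow)$reaction_limited, tolerance = 1e-6)
})

test_that("FRET and SS 2D affinities differ by exactly (K_A+1)/K_A", {
  for (seed in 1:15) {
    p <- draw_fundamental(seed, dilute = TRUE)
    K_A <- affinities(p)$K_A
    ratio <- reduce_to_effective(p, "FRET")$K_a / reduce_to_effective(p, "SS")$K_a
    expect_equal(ratio, (K_A + 1) / K_A, tolerance = 1e-10)
  }
})

test_that("meta-state projection groups species as the assay sees them", {
  traj <- data.frame(time = 0, R = 1, L = 1, RL_star = 2, RL = 3, C = 4)
  fr <- project_trajectory(traj, "FRET")
  expect_equal(unlist(fr[c("R", "L", "C")]), c(R = 3, L = 3, C = 7))
  expect_equal(project_trajectory(traj, "PBA")$RL, 5)
  expect_equal(project_trajectory(traj, "SS")$C, 4) # bound means C only
  # grouping preserves mass
  tot <- conserved_totals(unlist(traj[-1]))
  expect_equal(fr$R + fr$C, tot$R_total)
  expect_equal(fr$L + fr$C, tot$L_total)
})

test_that("inversion round-trips every determined constant to 1e-10", {
  for (seed in 1:10) {
    for (kind in c("PBA", "PBB", "FRET", "SS")) {
      p <- draw_fundamental(seed, dilute = needs_dilution(kind))
      eff <- reduce_to_effective(p, kind)
      inv <- invert_effective(eff, p)
      if (inv$determined[["k_plus"]]) {
        expect_equal(inv$k_plus, p$k_plus, tolerance = 1e-10)
      }
      if (inv$determined[["k_minus"]]) {
        expect_equal(inv$k_minus, p$k_minus, tolerance = 1e-10)
      }
      if (inv$determined[["K_A"]]) {
        expect_equal(inv$K_A, affinities(p)$K_A, tolerance = 1e-10)
      }
    }
  }
})

test_that("the FRET on-rate carries no ligand information", {
  p <- draw_fundamental(3, dilute = TRUE)
  inv <- invert_effective(reduce_to_effective(p, "FRET"), p)
  expect_false(inv$determined[["k_plus"]])
  expect_true(is.na(inv$k_plus))
  expect_true(inv$determined[["K_A"]]) # the off-rate does carry K_A
})

test_that("PBA inversion returns the off-rate exactly", {
  p <- draw_fundamental(8)
  eff <- reduce_to_effective(p, "PBA")
  expect_identical(invert_effective(eff, p)$k_minus, eff$k_off)
})

test_that("effective simulation conserves mass and reaches K_a equilibrium", {
  p <- draw_fundamental(9, dilute = TRUE)
  eff <- reduce_to_effective(p, "SS")
  tr <- simulate_effective(eff, c(R = 1, L = 0.7, C = 0),
                           c(0, 10^seq(-2, 4, length.out = 50)))
  last <- tr[nrow(tr), ]
  # two-state equilibrium: C/(R*L) = K_a
  expect_equal(last$C / (last$R * last$L), eff$K_a, tolerance = 1e-6)
  expect_equal(tr$R + tr$C, rep(1, nrow(tr)), tolerance = 1e-9)
  # frozen on-rate keeps the system unbound
  eff0 <- effective_constants("SS", "2D", k_on = 0, k_off = 1)
  tr0 <- simulate_effective(eff0, c(R = 1, L = 1, C = 0), seq(0, 5, 1))
  expect_equal(tr0$C, rep(0, nrow(tr0)))
})

test_that("reduction deviation is small at strong separation and shrinks with it", {
  for (kind in c("PBA", "PBB", "FRET", "SS")) {
    p <- draw_fundamental(12, dilute = needs_dilution(kind))
    d10 <- validate_reduction(p, kind, 10)$max_rel_dev
    d1000 <- validate_reduction(p, kind, 1000)$max_rel_dev
    expect_lt(d1000, 1e-2)
    expect_lt(d1000, d10)
  }
  # frozen binding: both descriptions identically unbound
  p0 <- fundamental_constants("2D", 1, 1, 1, 1, k_plus = 0, k_minus = 1)
  expect_equal(validate_reduction(p0, "SS", 100)$max_rel_dev, 0)
  expect_error(validate_reduction(draw_fundamental(1), "SS", 5), ">= 10")
})
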