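test_that("mass-action derivatives respect conservation and symmetry", {
  for (seed in 1:20) {
    p <- draw_fundamental(seed)
    set.seed(seed + 1000)
    st <- species_state(R = runif(1, 0, 2), L = runif(1, 0, 2),
                        RL_star = runif(1, 0, 1), RL = runif(1, 0, 1),
                        C = runif(1, 0, 1))
    d <- rate_equations(p, st)
    expect_identical(d[["R"]], d[["L"]])
    expect_equal(d[["R"]] + d[["RL_star"]] + d[["RL"]] + d[["C"]], 0,
                 tolerance = 1e-12)
    expect_equal(d[["L"]] + d[["RL_star"]] + d[["RL"]] + d[["C"]], 0,
                 tolerance = 1e-12)
  }
})

test_that("derivatives vanish with nothing to react and with frozen steps", {
  p <- draw_fundamental(3)
  expect_equal(unname(rate_equations(p, species_state(R = 1, L = 0))),
               rep(0, 5))
  frozen <- fundamental_constants("2D", p$d_plus, p$d_minus, p$e_plus,
                                  p$e_minus, k_plus = 0, k_minus = 0)
  d <- rate_equations(frozen, species_state(R = 0, L = 0, RL = 2, C = 1))
  expect_identical(d[["C"]], 0)
})

test_that("negative concentrations are rejected", {
  p <- draw_fundamental(1)
  expect_error(rate_equations(p, c(R = -1, L = 1, RL_star = 0, RL = 0, C = 0)),
               "negative")
  expect_error(species_state(R = -0.1, L = 1), "non-negative")
})

test_that("irreversible binding funnels all limiting mass into the complex", {
  p <- fundamental_constants("2D", d_plus = 5, d_minus = 0, e_plus = 2,
                             e_minus = 0, k_plus = 3, k_minus = 0)
  tr <- simulate_kinetics(p, species_state(R = 1, L = 0.4),
                          c(0, 10^seq(-2, 3, length.out = 40)))
  expect_equal(tr$C[nrow(tr)], 0.4, tolerance = 1e-6)
  expect_lt(conservation_drift(tr), 1e-8)
})

test_that("long-time integration reaches the algebraic equilibrium", {
  for (seed in 1:10) {
    p <- draw_fundamental(seed)
    eq <- equilibrium_state(p, R_total = 1.5, L_total = 1)
    tr <- simulate_kinetics(p, species_state(R = 1.5, L = 1),
                            c(0, 10^seq(-2, 3, length.out = 60)))
    last <- unlist(tr[nrow(tr), c("R", "L", "RL_star", "RL", "C")])
    expect_equal(unname(last), unname(eq[names(last)]), tolerance = 1e-6)
    expect_lt(conservation_drift(tr), 1e-8)
  }
})

test_that("equilibrium is invariant under uniform scaling of all six rates", {
  p <- draw_fundamental(7)
  p2 <- fundamental_constants("2D", 2 * p$d_plus, 2 * p$d_minus, 2 * p$e_plus,
                              2 * p$e_minus, 2 * p$k_plus, 2 * p$k_minus)
  expect_equal(equilibrium_state(p, 1.2, 0.8), equilibrium_state(p2, 1.2, 0.8),
               tolerance = 1e-12)
})

test_that("equilibrium satisfies detailed balance of every step", {
  for (seed in 1:10) {
    p <- draw_fundamental(seed + 50)
    aff <- affinities(p)
    eq <- equilibrium_state(p, 2, 1.3)
    expect_equal(eq[["RL_star"]] / (eq[["R"]] * eq[["L"]]), aff$K_D,
                 tolerance = 1e-8)
    expect_equal(eq[["RL"]] / eq[["RL_star"]], aff$E, tolerance = 1e-8)
    expect_equal(eq[["C"]] / eq[["RL"]], aff$K_A, tolerance = 1e-8)
    tot <- conserved_totals(eq)
    expect_equal(tot$R_total, 2, tolerance = 1e-12)
    expect_equal(tot$L_total, 1.3, tolerance = 1e-12)
  }
})

test_that("equilibrium edge cases: no ligand, unit binding affinity, zero off-rate", {
  p <- draw_fundamental(2)
  eq <- equilibrium_state(p, 1, 0)
  expect_equal(unname(eq[c("L", "RL_star", "RL", "C")]), rep(0, 4))
  expect_equal(eq[["R"]], 1)
  p_unit <- fundamental_constants("2D", p$d_plus, p$d_minus, p$e_plus,
                                  p$e_minus, k_plus = 1.3, k_minus = 1.3)
  eq2 <- equilibrium_state(p_unit, 1, 1)
  expect_equal(eq2[["C"]], eq2[["RL"]], tolerance = 1e-12)
  p_zero <- fundamental_constants("2D", 1, 0, 1, 1, 1, 1)
  expect_error(equilibrium_state(p_zero, 1, 1), "off-rates")
})

test_that("times must be strictly increasing", {
  p <- draw_fundamental(1)
  expect_error(simulate_kinetics(p, species_state(1, 1), c(0, 1, 1)),
               "strictly increasing")
})
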