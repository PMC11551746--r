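test_that("mass-action derivatives match direct arithmetic and conserve strands", {
  # identity case: no flux anywhere
  r0 <- rate_constants(0, 0, 0, 0, 0, 0)
  d0 <- mass_action_derivatives(r0, reaction_state(36, 36, C1 = 3, C2 = 2, D = 1, E = 1))
  expect_equal(unname(d0), rep(0, 6))

  # single active step: dA/dt = -k1 * A * B
  r1 <- rate_constants(1e-3, 0, 0, 0, 0, 0)
  d1 <- mass_action_derivatives(r1, reaction_state(36, 36))
  expect_equal(d1[["A"]], -1.296)
  expect_equal(d1[["B"]], -1.296)
  expect_equal(d1[["C1"]], 1.296)

  # strand conservation: the filament strand flows through A, C1, C2, D
  for (s in 1:20) {
    r <- random_rates(s)
    set.seed(1000 + s)
    st <- reaction_state(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 10),
                         runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 10))
    d <- mass_action_derivatives(r, st)
    expect_lt(abs(d[["A"]] + d[["C1"]] + d[["C2"]] + d[["D"]]), 1e-12)
    expect_lt(abs(d[["B"]] + d[["C1"]] + d[["C2"]] + d[["D"]]), 1e-12)
    expect_equal(d[["D"]], d[["E"]])
  }

  # two-step scheme
  r2 <- rate_constants(1e-3, 1e-2, 5e-3, 1e-4)
  d2 <- mass_action_derivatives(r2, reaction_state(10, 10, C1 = 2, scheme = "two_step"))
  expect_equal(d2[["A"]], -(1e-3 * 100 - 1e-2 * 2))
  expect_lt(abs(d2[["A"]] + d2[["C1"]] + d2[["D"]]), 1e-15)

  expect_error(rate_constants(-1e-3, 0, 0, 0, 0, 0), class = "strandex_invalid_parameter")
  expect_error(rate_constants(1e-3, NA, 0, 0, 0, 0), class = "strandex_invalid_parameter")
})

test_that("simulation reproduces closed-form and trivial limits", {
  # all rates zero: nothing moves
  traj <- simulate_exchange(rate_constants(0, 0, 0, 0, 0, 0),
                            times = seq(0, 100, 10))
  expect_true(all(traj$A == 36) && all(traj$B == 36) && all(traj$D == 0))

  # irreversible second-order with equal substrates: A(t) = A0 / (1 + k1 A0 t)
  k1 <- 2e-4
  times <- seq(0, 800, 8)
  traj <- simulate_exchange(rate_constants(k1, 0, 0, 0, 0, 0), times = times)
  expected <- 36 / (1 + k1 * 36 * times)
  expect_rel_equal(traj$A, expected, 1e-6)

  # first row equals the initial state
  st0 <- reaction_state(20, 30, C1 = 1)
  traj <- simulate_exchange(random_rates(3), st0, times = seq(0, 50, 5))
  expect_equal(unlist(traj[1, -1]), st0[c("A", "B", "C1", "C2", "D", "E")],
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(simulate_exchange(random_rates(1), times = c(0, 10, 5)),
               class = "strandex_invalid_parameter")
  expect_error(simulate_exchange(random_rates(1), times = c(5, 10)),
               class = "strandex_invalid_parameter")
})

test_that("trajectories conserve both strands and keep E = D", {
  for (s in 1:15) {
    r <- random_rates(s + 40)
    traj <- simulate_exchange(r, times = seq(0, 500, 20))
    expect_lt(max(abs(traj$A + traj$C1 + traj$C2 + traj$D - 36)), 1e-6)
    expect_lt(max(abs(traj$B + traj$C1 + traj$C2 + traj$D - 36)), 1e-6)
    expect_lt(max(abs(traj$E - traj$D)), 1e-9)
    expect_true(all(unlist(traj[-1]) >= 0))
  }
})

test_that("irreversible forward chain is monotone", {
  r <- rate_constants(2e-4, 0, 5e-3, 0, 2e-3, 0)
  traj <- simulate_exchange(r, times = seq(0, 1000, 10))
  expect_true(all(diff(traj$A) <= 1e-10))
  expect_true(all(diff(traj$D) >= -1e-10))
})

test_that("algebraic equilibrium zeroes the derivatives and matches long-time simulation", {
  for (s in 1:10) {
    r <- random_rates(s + 70)
    eq <- algebraic_equilibrium(r)
    d <- mass_action_derivatives(r, unlist(eq))
    expect_lt(max(abs(d)), 1e-9)
  }

  # binding-only reduction A + B <-> C1 has a quadratic closed form
  r <- rate_constants(1e-3, 1e-2, 0, 1e-3, 0, 1e-4)
  K1 <- 0.1
  disc <- (36 + 36 + 1 / K1)^2 - 4 * 36 * 36
  C1_closed <- ((36 + 36 + 1 / K1) - sqrt(disc)) / 2
  eq <- algebraic_equilibrium(r)
  expect_rel_equal(eq$C1, C1_closed, 1e-9)
  expect_equal(eq$C2, 0)

  # all forward rates zero: equilibrium is the free species
  r0f <- rate_constants(0, 1e-2, 0, 1e-3, 0, 1e-4)
  eq0 <- algebraic_equilibrium(r0f)
  expect_equal(eq0$A, 36, tolerance = 1e-9)
  expect_equal(eq0$D, 0)

  expect_error(algebraic_equilibrium(rate_constants(1e-3, 0, 1e-3, 1e-3, 1e-3, 1e-3)),
               class = "strandex_undefined_equilibrium")
})

test_that("equilibrium constants are componentwise rate ratios", {
  eq <- equilibrium_constants(rate_constants(1e-3, 1e-2, 5e-3, 1e-3, 2e-3, 1e-4))
  expect_equal(eq$K1, 0.1)
  expect_equal(eq$K2, 5)
  expect_equal(eq$K3, 20)
  expect_equal(eq$K_total, 10)

  equ <- equilibrium_constants(rate_constants(1e-3, 1e-3, 5e-2, 5e-2, 1e-4, 1e-4))
  expect_equal(unlist(equ), c(K1 = 1, K2 = 1, K3 = 1, K_total = 1))

  for (s in 1:10) {
    r <- random_rates(s + 100)
    eq <- equilibrium_constants(r)
    expect_identical(eq$K_total, eq$K1 * eq$K2 * eq$K3)
    expect_true(all(unlist(eq) > 0))
  }
  expect_error(equilibrium_constants(rate_constants(1e-3, 0, 1e-3, 1e-3, 1e-3, 1e-3)),
               class = "strandex_undefined_equilibrium")
})

test_that("relative equilibrium changes are plain fold ratios", {
  base <- equilibrium_constants(rate_constants(1e-3, 1e-2, 5e-3, 1e-3, 2e-3, 1e-4))
  expect_equal(unlist(relative_equilibrium_change(base, base)),
               c(K1 = 1, K2 = 1, K3 = 1, K_total = 1))
  expect_equal(relative_equilibrium_change(list(K_total = 6), list(K_total = 1))$K_total, 6)
  set.seed(9)
  f <- 10^runif(4, -1, 1)
  scaled <- as.list(unlist(base) * f)
  expect_equal(unname(unlist(relative_equilibrium_change(scaled, base))),
               unname(f), tolerance = 1e-12)
  expect_error(relative_equilibrium_change(base, list(K1 = 0)),
               class = "strandex_division_error")
})
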