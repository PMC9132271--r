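test_that("carrying capacity follows the soil-moisture power law", {
  p <- capacity_params(kappa_max = 100, nu = 0.5)
  expect_equal(carrying_capacity(150, 150, p), 100)
  expect_equal(carrying_capacity(150 / 4, 150, p), 50)

  # nu = 0 fixes the capacity regardless of moisture
  p0 <- capacity_params(kappa_max = 250, nu = 0)
  w <- seq(0, 150, by = 10)
  expect_equal(carrying_capacity(w, 150, p0), rep(250, length(w)))

  # dry-soil floor with nu > 0
  expect_equal(carrying_capacity(0, 150, capacity_params(100, 2)), 1e-6)

  # log K linear in log(W/W*) with slope nu, recovered by regression
  for (nu in c(0.2, 0.5, 1, 2)) {
    w <- seq(15, 150, length.out = 40)
    k <- carrying_capacity(w, 150, capacity_params(100, nu))
    slope <- coef(lm(log(k) ~ log(w / 150)))[[2]]
    expect_equal(slope, nu, tolerance = 1e-6)
  }

  expect_error(carrying_capacity(200, 150, p), class = "pcmp_invariant_violation")
  expect_error(carrying_capacity(50, -1, p), class = "pcmp_invalid_site")
})

test_that("diapause probabilities honor the photoperiod-change gates", {
  p <- diapause_params()
  # half-saturation: each sigmoid is 1/2, product 1/4
  expect_equal(diapause_induction_prob(p$beta_d1, p$beta_t1, -0.01, p), 0.25)
  expect_equal(diapause_termination_prob(p$beta_d2, p$beta_t2, +0.01, p), 0.25)

  # outside the gate the probability is exactly zero
  expect_equal(diapause_induction_prob(10, 10, +0.01, p), 0)
  expect_equal(diapause_induction_prob(10, 10, 0, p), 0)
  expect_equal(diapause_termination_prob(20, 25, -0.01, p), 0)
  expect_equal(diapause_termination_prob(20, 25, 0, p), 0)

  # saturated limits
  steep <- diapause_params(alpha_d1 = 1e3, alpha_t1 = 1e3,
                           alpha_d2 = 1e3, alpha_t2 = 1e3)
  expect_equal(diapause_induction_prob(steep$beta_d1 - 5, steep$beta_t1 - 10,
                                       -0.01, steep), 1, tolerance = 1e-6)
  expect_equal(diapause_termination_prob(steep$beta_d2 + 5, steep$beta_t2 + 10,
                                         +0.01, steep), 1, tolerance = 1e-6)
})

test_that("diapause probabilities are bounded, monotone, and overflow-free", {
  set.seed(31)
  extreme <- diapause_params(alpha_d1 = 10^5.10, alpha_d2 = 10^3.84,
                             alpha_t1 = 10^4.70, alpha_t2 = 10^2.42)
  for (rep in 1:50) {
    d <- runif(1, 0, 24); ta <- runif(1, -20, 45); dd <- runif(1, -0.1, 0.1)
    z1 <- diapause_induction_prob(d, ta, dd, extreme)
    z2 <- diapause_termination_prob(d, ta, dd, extreme)
    expect_true(is.finite(z1) && z1 >= 0 && z1 <= 1)
    expect_true(is.finite(z2) && z2 >= 0 && z2 <= 1)
  }
  # monotone in each argument
  mild <- diapause_params(alpha_d1 = 2, alpha_d2 = 2, alpha_t1 = 1, alpha_t2 = 1)
  d_grid <- seq(8, 16, 0.5)
  expect_true(all(diff(diapause_induction_prob(d_grid, 20, -0.01, mild)) <= 0))
  expect_true(all(diff(diapause_induction_prob(12, d_grid + 10, -0.01, mild)) <= 0))
  expect_true(all(diff(diapause_termination_prob(d_grid, 12, 0.01, mild)) >= 0))
  expect_true(all(diff(diapause_termination_prob(12, d_grid, 0.01, mild)) >= 0))
})

test_that("hard-threshold diapause switches use the published cut-offs", {
  expect_true(threshold_diapause(20, 13)$diapause_on)
  expect_false(threshold_diapause(22, 13)$diapause_on)
  expect_true(threshold_diapause(11, 10.5)$break_on)
  expect_false(threshold_diapause(10, 10.5)$break_on)
})

test_that("stage derivatives route flows according to the diapause split", {
  rates <- list(d_E = 0.1, d_L = 0.1, d_P = 0.3, m_E = 0.01, m_L = 0.02,
                m_P = 0.02, m_A = 0.05, o_v = 3, z1 = 0, z2 = 0, K = 100)
  zero <- initial_state(E = 0, E_dia = 0, L = 0, P = 0, A = 0)
  expect_equal(unname(stage_derivatives(zero, rates)), rep(0, 5))

  # z1 = 1: all oviposition routed to the diapause pool
  r1 <- rates; r1$z1 <- 1
  s <- initial_state(E = 10, E_dia = 5, L = 0, P = 0, A = 7)
  d <- stage_derivatives(s, r1)
  expect_equal(d[["E_dia"]], 3 * 7)
  expect_equal(d[["E"]], -(0.01 + 0.1) * 10)

  expect_error(stage_derivatives(s, within(rates, K <- 0)),
               class = "pcmp_invalid_capacity")
})

test_that("stage-flow bookkeeping closes on random states", {
  set.seed(77)
  for (rep in 1:25) {
    rates <- list(d_E = runif(1, 0, 0.3), d_L = runif(1, 0, 0.3),
                  d_P = runif(1, 0, 0.5), m_E = runif(1, 0.01, 0.2),
                  m_L = runif(1, 0.01, 0.2), m_P = runif(1, 0.01, 0.2),
                  m_A = runif(1, 0.01, 0.3), o_v = runif(1, 0, 5),
                  z1 = runif(1), z2 = runif(1), K = runif(1, 10, 500))
    s <- initial_state(E = runif(1, 0, 1e3), E_dia = runif(1, 0, 1e4),
                       L = runif(1, 0, 500), P = runif(1, 0, 200),
                       A = runif(1, 0, 300))
    d <- stage_derivatives(s, rates)
    # development transfers cancel pairwise; only births and deaths remain
    expected_total <- rates$o_v * s[["A"]] -
      (rates$m_E * s[["E"]] + (rates$m_L + s[["L"]] / rates$K) * s[["L"]] +
         rates$m_P * s[["P"]] + rates$m_A * s[["A"]])
    expect_equal(sum(d), expected_total, tolerance = 1e-12)
  }
})

test_that("the daily step matches R-side derivatives and handles decay", {
  rates <- list(d_E = 0, d_L = 0, d_P = 0, m_E = 0.1, m_L = 0.1, m_P = 0.1,
                m_A = 0.1, o_v = 0, z1 = 0, z2 = 0, K = 100)
  zero <- initial_state(E = 0, E_dia = 0, L = 0, P = 0, A = 0)
  expect_equal(unname(step_population(zero, rates)), rep(0, 5))

  # pure death process: every stage decays monotonically toward zero
  s <- initial_state(E = 100, E_dia = 0, L = 50, P = 20, A = 10)
  for (i in 1:30) {
    s2 <- step_population(s, rates)
    expect_true(all(s2 <= unclass(s) + 1e-12))
    s <- initial_state(E = s2[["E"]], E_dia = s2[["E_dia"]], L = s2[["L"]],
                       P = s2[["P"]], A = s2[["A"]])
  }
  expect_lt(s[["E"]], 100 * exp(-0.1 * 30) * 1.05)
})

test_that("simulation preserves zero states, determinism, and nonnegativity", {
  env <- test_world()$env
  params <- model_params()
  zero <- initial_state(E = 0, E_dia = 0, L = 0, P = 0, A = 0)
  traj0 <- simulate_population(env, params, init = zero)
  expect_true(all(as.matrix(traj0[, c("E", "E_dia", "L", "P", "A")]) == 0))

  t1 <- simulate_population(env, params)
  t2 <- simulate_population(env, params)
  expect_identical(t1, t2)
  m <- as.matrix(t1[, c("E", "E_dia", "L", "P", "A")])
  expect_true(all(is.finite(m)) && all(m >= 0))
})

test_that("long runs stay finite and nonnegative", {
  wx <- generate_weather(weather_gen_config(seed = 3), n_years = 100)
  env <- build_environment(wx, tokyo_site())
  traj <- simulate_population(env, model_params())
  m <- as.matrix(traj[, c("E", "E_dia", "L", "P", "A")])
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0))
})

test_that("periodic forcing settles onto an annual cycle", {
  wx <- sinusoid_weather(10)
  env <- build_environment(wx, tokyo_site())
  params <- model_params(capacity = capacity_params(kappa_max = 100, nu = 0))
  traj <- simulate_population(env, params)
  yr <- as.integer(format(traj$date, "%Y"))
  a9 <- traj$A[yr == 2009][1:365]
  a10 <- traj$A[yr == 2010][1:365]
  expect_lt(max(abs(a10 - a9)) / max(a10), 0.01)
})

test_that("doubling the maximum capacity does not reduce the adult peak", {
  env <- test_world()$env
  peak_at <- function(kmax) {
    p <- model_params(capacity = capacity_params(kappa_max = kmax, nu = 1))
    traj <- simulate_population(env, p)
    yr <- as.integer(format(traj$date, "%Y"))
    max(traj$A[yr > 2001])
  }
  peaks <- vapply(c(50, 100, 200), peak_at, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("larval crowding equilibrium matches a root-finding oracle", {
  # constant benign environment: L settles where inflow balances
  # (m_L + d_L + L/K) L; solve that balance independently and compare
  rates_const <- list(d_E = 0.1, d_L = 0.12, d_P = 0.3, m_E = 0.02,
                      m_L = 0.03, m_P = 0.03, m_A = 0.08, o_v = 3,
                      z1 = 0, z2 = 0, K = 200)
  s <- initial_state(E = 50, E_dia = 0, L = 10, P = 5, A = 20)
  for (i in 1:4000) s <- do.call(initial_state, as.list(step_population(s, rates_const)))
  # at equilibrium the full five-stage balance must hold; check the larval one
  with(rates_const, {
    inflow <- d_E * s[["E"]]
    loss <- (m_L + d_L + s[["L"]] / K) * s[["L"]]
    l_root <- uniroot(function(L) inflow - (m_L + d_L + L / K) * L,
                      c(0, 1e6))$root
    expect_lt(abs(s[["L"]] - l_root) / l_root, 0.005)
    expect_lt(abs(inflow - loss) / loss, 0.005)
  })
})
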