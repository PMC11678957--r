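test_that("single Euler step reproduces hand arithmetic", {
  # rest state with zero demand is a fixed point
  p <- model_parameters(2.1e-2, 1.04e-2, 0, 0)
  s <- fatigue_step(list(t = 0, ma = 0, mf = 0), mad = 0, params = p,
                    m0 = 418.55, dt = 0.1)
  expect_equal(s$ma, 0)
  expect_equal(s$mf, 0)
  expect_equal(s$t, 0.1)

  # maximal step demand from rest: dMA = mad * M0 * alpha_a
  s <- fatigue_step(list(t = 0, ma = 0, mf = 0), mad = 418.55, params = p,
                    m0 = 418.55, dt = 0.1)
  expect_equal(s$ma, 0.1 * 418.55 * 418.55 * 2.1e-2, tolerance = 1e-12)

  # deactivation limb: dMA = (mad - MA) * MA * beta_d
  p2 <- model_parameters(1e-3, 1e-2, 0, 0)
  s <- fatigue_step(list(t = 0, ma = 300, mf = 0), mad = 100, params = p2,
                    m0 = 1000, dt = 0.1)
  expect_equal(s$ma, 300 + 0.1 * (100 - 300) * 300 * 1e-2) # 240
})

test_that("step rejects invalid input and warns on the overshoot bound", {
  p <- default_params()
  expect_error(fatigue_step(list(t = 0, ma = NA, mf = 0), 1, p, 10, 0.1),
               "non-finite")
  expect_error(fatigue_step(list(t = 0, ma = 0, mf = 0), -1, p, 10, 0.1),
               "non-negative")
  # dt * MP * alpha_a >= 1 triggers the stability warning but still steps
  pf <- model_parameters(9.9, 9.96, 9.99e-2, 1.55e-2)
  expect_warning(
    s <- fatigue_step(list(t = 0, ma = 0, mf = 0), 20, pf, 25, 0.1),
    class = "sprintfatigue_stability")
  expect_true(is.finite(s$ma))
})

test_that("composing single steps matches the compiled simulation", {
  demand <- demand_profile(c(0, 5, 5, 2, 8, 8, 0))
  p <- model_parameters(5e-3, 8e-3, 0.03, 0.02)
  tr <- simulate_fatigue(demand, p, 10, init = list(ma = 0, mf = 0))
  st <- list(t = 0, ma = 0, mf = 0)
  for (k in seq_len(length(demand$values) - 1)) {
    for (s in 1:10) st <- fatigue_step(st, demand$values[k], p, 10, 0.1)
  }
  n <- length(tr$ma)
  expect_equal(st$ma, tr$ma[n], tolerance = 1e-12)
  expect_equal(st$mf, tr$mf[n], tolerance = 1e-12)
})

test_that("zero demand from rest stays at the all-available fixed point", {
  d <- constant_demand(0, 30)
  tr <- simulate_fatigue(d, default_params(), 100, init = list(ma = 0, mf = 0))
  expect_true(all(tr$ma == 0))
  expect_true(all(tr$mf == 0))
  expect_true(all(tr$mp == 100))
})

test_that("simulation conserves capacity and respects compartment bounds", {
  set.seed(101)
  for (i in 1:50) {
    m0 <- runif(1, 100, 2000)
    demand <- random_step_demand(duration = 40, level_max = m0)
    p <- random_bounded_params(m0)
    tr <- simulate_fatigue(demand, p, m0, init = list(ma = 0, mf = 0))
    expect_true(max(abs(tr$ma + tr$mf + tr$mp - m0)) <= 1e-9 * m0)
    expect_true(min(tr$ma) >= 0)
    expect_true(min(tr$mf) >= 0)
    expect_true(min(tr$mp) >= -1e-12 * m0)
  }
})

test_that("activation never exceeds a constant demand it started below", {
  set.seed(7)
  for (i in 1:20) {
    m0 <- runif(1, 50, 500)
    dlev <- runif(1, 0.2, 0.95) * m0
    p <- random_bounded_params(m0)
    tr <- simulate_fatigue(constant_demand(dlev, 60), p, m0,
                           init = list(ma = runif(1, 0, dlev), mf = 0))
    expect_true(max(tr$ma) <= dlev + 1e-9 * m0)
  }
})

test_that("trajectory exposes an exact whole-second evaluation view", {
  d <- constant_demand(50, 12)
  tr <- simulate_fatigue(d, default_params(), 100, init = list(ma = 0, mf = 0))
  expect_equal(tr$eval_view$t, 0:12)
  idx <- match(0:12, round(tr$times, 9))
  expect_equal(tr$eval_view$ma, tr$ma[idx])
  expect_error(simulate_fatigue(demand_profile(5), default_params(), 10),
               "at least one second")
})

test_that("closed-form activation agrees with independent fine integration", {
  # limits
  expect_equal(closed_form_activation(50, 100, 1e-3, 0, ma0 = 3), 3)
  expect_equal(closed_form_activation(50, 100, 1e-3, 1e9, ma0 = 0), 50)
  expect_error(closed_form_activation(100, 100, 1e-3, 1), "degenerate")
  # independent oracle: RK4 on dMA/dt = (D-MA)(M0-MA)*alpha at h = 1e-4
  f <- function(x) (50 - x) * (100 - x) * 1e-3
  x <- 0; h <- 1e-4
  for (i in seq_len(60 / h)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(closed_form_activation(50, 100, 1e-3, 60, 0), x,
               tolerance = 1e-6)
})

test_that("closed-form decay and fatigue match direct arithmetic", {
  expect_equal(closed_form_decay(0, 1e-2, c(0, 5, 50)), c(0, 0, 0))
  expect_equal(closed_form_decay(100, 1e-2, 0), 100)
  expect_equal(closed_form_decay(100, 1e-2, 1), 50)
  expect_equal(closed_form_fatigue(100, 0.05, 0.05, 0), 0)
  expect_equal(closed_form_fatigue(100, 0.05, 0.05, 1e9), 100 * 0.05 / 0.05)
  expect_equal(closed_form_fatigue(100, 0.05, 0.05, 20), 100 * (1 - exp(-1)))
  # documented R = 0 special case: linear growth
  expect_equal(closed_form_fatigue(10, 0.02, 0, 30), 10 * 0.02 * 30)
})

test_that("Euler at 0.1 s tracks the closed forms and converges first order", {
  # activation limb (F = R = 0)
  p <- model_parameters(1e-3, 1e-3, 0, 0)
  tr <- simulate_fatigue(constant_demand(50, 60), p, 100,
                         init = list(ma = 0, mf = 0))
  ex <- closed_form_activation(50, 100, 1e-3, 60, 0)
  expect_lt(abs(tail(tr$eval_view$ma, 1) - ex) / ex, 1e-3)

  # deactivation limb, instance resolved by the step size
  p2 <- model_parameters(1e-5, 1e-3, 0, 0)
  tr2 <- simulate_fatigue(constant_demand(0, 60), p2, 100,
                          init = list(ma = 20, mf = 0))
  ex2 <- closed_form_decay(20, 1e-3, 60)
  expect_lt(abs(tail(tr2$eval_view$ma, 1) - ex2) / ex2, 1e-3)

  # fatigue limb with activation pinned at the demand
  p3 <- model_parameters(1e-5, 1e-5, 0.05, 0.05)
  tr3 <- simulate_fatigue(constant_demand(100, 60), p3, 1e4,
                          init = list(ma = 100, mf = 0))
  ex3 <- closed_form_fatigue(100, 0.05, 0.05, 60)
  expect_lt(abs(tail(tr3$eval_view$mf, 1) - ex3) / ex3, 1e-3)

  # halving dt roughly halves the activation error
  errs <- sapply(c(0.1, 0.05), function(dt) {
    t <- simulate_fatigue(constant_demand(50, 60), p, 100,
                          init = list(ma = 0, mf = 0), dt = dt)
    abs(tail(t$eval_view$ma, 1) - ex) / ex
  })
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.2)
})

test_that("sustained maximal demand: rise, then monotone fatigue decline", {
  p <- model_parameters(2.10e-2, 1.04e-2, 2.40e-2, 1.19e-2)
  tr <- simulate_fatigue(constant_demand(435, 60, unit = "N"), p, 418.55,
                         init = list(ma = 0, mf = 0))
  ev <- tr$eval_view$ma
  pk <- which.max(ev)
  expect_lte(ev[pk] - 418.55, 1e-9)
  expect_lt(tr$eval_view$t[pk], 5) # rises within the first seconds
  expect_true(all(diff(ev[pk:length(ev)]) <= 1e-9)) # then declines
})

test_that("baseline model matches the enhanced one on sustained demand", {
  d <- constant_demand(435, 60, unit = "N")
  sns <- simulate_sns(d, f = 2.45e-2, r = 1.15e-2, m0 = 435)
  enh <- simulate_fatigue(d, model_parameters(2.1e-2, 1.04e-2, 2.4e-2,
                                              1.19e-2), 418.55)
  # both start at the demanded level and decline as fatigue accumulates
  expect_equal(sns$eval_view$ma[1], 435)
  expect_true(all(diff(sns$eval_view$ma) < 0))
  expect_gt(r_squared(enh$eval_view$ma, sns$eval_view$ma), 0.95)
})

test_that("baseline model jumps with demand steps and can go negative", {
  prof <- gen_literature_protocols()
  # stepped drill: per-second activation change attains the demand jump
  drill <- prof$drill_1min
  sns_d <- simulate_sns(drill, f = 0.05, r = 0.05, m0 = 20)
  expect_equal(max(abs(diff(sns_d$eval_view$ma))),
               max(abs(diff(drill$values))), tolerance = 1e-9)
  # intermittent treadmill protocol: negative activation appears
  sns_t <- simulate_sns(prof$treadmill_15min, f = 0.05, r = 0.05, m0 = 27)
  expect_lt(min(sns_t$ma), 0)
  # identical demand through the enhanced model stays non-negative
  enh_t <- simulate_fatigue(prof$treadmill_15min,
                            model_parameters(5e-4, 5e-3, 0.05, 0.05), 27)
  expect_gte(min(enh_t$ma), 0)
})

test_that("trajectory CSV round-trips the evaluation view", {
  d <- constant_demand(50, 10)
  tr <- simulate_fatigue(d, default_params(), 100, init = list(ma = 0, mf = 0))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t", "mad", "ma", "mf", "mp"))
  expect_equal(df$ma, tr$eval_view$ma, tolerance = 1e-12)
  expect_equal(df$mad, d$values)
})
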