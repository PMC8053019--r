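test_that("double-Monod growth law matches direct scalar evaluation", {
  p <- tp()
  # both saturation factors equal 1/2 at their half-saturation constants
  expect_equal(growth_rate(p$Ks, p$Kc, p), p$mumax / 4)
  expect_equal(growth_rate(p$Ks, p$Kc, p), 0.0375)
  expect_equal(growth_rate(0, 3, p), 0)
  # independent term-by-term evaluation at S = 200, Co = 0.5
  mu_oracle <- 0.15 * (200 / (100 + 200)) * (0.5 / (2 + 0.5))
  expect_equal(growth_rate(200, 0.5, p), mu_oracle)
  expect_error(growth_rate(-1, 1, p), "non-negative")
  expect_error(growth_rate(1, -1, p), "non-negative")
})

test_that("growth rate is bounded by mumax and monotone in each argument", {
  p <- tp()
  S <- seq(0, 500, length.out = 40)
  Co <- seq(0, 20, length.out = 40)
  g <- outer(S, Co, function(s, c) growth_rate(s, c, p))
  expect_true(all(g >= 0))
  expect_true(all(g < p$mumax))
  # increasing along rows (S) and columns (Co)
  expect_true(all(diff(g) >= 0))
  expect_true(all(t(diff(t(g))) >= 0))
})

test_that("plant right-hand side reproduces the mass balances term by term", {
  p <- tp()
  # washout / no flow: no biomass, no dilution
  d0 <- plant_rhs(c(0, 0, 50, 3), c(D = 0, KLa = 0), 0, p)
  expect_equal(unname(d0[1:2]), c(0, 0))
  # all transport terms carry D or KLa: pure reaction remains
  x <- c(X = 400, Xr = 900, S = 60, Co = 2)
  mu <- growth_rate(60, 2, p)
  expect_equal(unname(plant_rhs(x, c(0, 0), 0, p)),
               c(mu * 400, 0, -mu * 400 / p$Y, -p$K0 * mu * 400 / p$Y))
  # independent term-by-term hand computation
  X <- 500; Xr <- 800; S <- 50; Co <- 3; D <- 0.05; KLa <- 5
  mu <- 0.15 * S / (100 + S) * Co / (2 + Co)
  oracle <- c(
    mu * X - D * 1.6 * X + 0.6 * D * Xr,
    D * 1.6 * X - D * 0.8 * Xr,
    -mu * X / 0.65 - 1.6 * D * S + D * 200,
    -0.5 * mu * X / 0.65 - D * 1.6 * Co + D * 0.5 + KLa * (10 - Co))
  expect_equal(unname(plant_rhs(c(X, Xr, S, Co), c(D, KLa), 0, p)), oracle)
})

test_that("additive and built-in influent-disturbance forms coincide", {
  p <- tp()
  io <- rand_inputs(50)
  G <- as.vector(ts_G())
  for (k in 1:50) {
    a <- plant_rhs(io$x[k, ], io$u[k, ], io$ds[k], p)
    b <- plant_rhs(io$x[k, ], io$u[k, ], 0, p) + G * io$u[k, 1] * io$ds[k]
    expect_equal(unname(a), unname(b), tolerance = 1e-14)
  }
})

test_that("scenario evaluation applies the sinusoid and kinetic windows", {
  p <- tp()
  sc <- disturbance_scenario()
  expect_equal(scenario_eval(0, sc, p)$delta_sin, 0)
  # quarter period: amplitude 5 percent of Sin = 200
  expect_equal(scenario_eval(6, sc, p)$delta_sin, 10)
  # inside the mumax window (days 10-12): 10 percent increase
  ev <- scenario_eval(10.5 * 24, sc, p)
  expect_equal(ev$effective$mumax, 1.1 * 0.15)
  expect_equal(ev$effective$Kc, p$Kc)
  # inside the Kc window (days 50-52)
  ev2 <- scenario_eval(51 * 24, sc, p)
  expect_equal(ev2$effective$Kc, 1.1 * 2)
  expect_equal(ev2$effective$mumax, p$mumax)
  # outside all windows
  ev3 <- scenario_eval(30 * 24, sc, p)
  expect_equal(ev3$effective$mumax, p$mumax)
  expect_error(scenario_eval(-1, sc, p), "non-negative")
  expect_error(disturbance_scenario(kinetic_events = list(
    list(param = "Ks", change = 0.1, start = 0, duration = 1))), "unknown")
})

test_that("analytic influent-derivative matches finite differences", {
  p <- tp()
  sc <- disturbance_scenario()
  h <- 1e-5
  for (t in c(0.3, 7, 100)) {
    fd <- (scenario_eval(t + h, sc, p)$delta_sin -
             scenario_eval(t - h, sc, p)$delta_sin) / (2 * h)
    expect_equal(delta_sin_deriv(t, sc, p), fd, tolerance = 1e-6)
  }
})

test_that("integration preserves non-negativity of concentrations", {
  p <- tp()
  rhs <- function(t, x, parms) {
    list(plant_rhs(pmax(x, 0), c(D = 0.08, KLa = 4),
                   10 * sin(2 * pi * t / 24), p))
  }
  # start at a domain corner with zero dissolved oxygen
  sol <- deSolve::ode(y = c(X = 50, Xr = 100, S = 0, Co = 0),
                      times = seq(0, 240, by = 1), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  expect_true(min(sol[, -1]) >= -1e-6)
})
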