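# Reference parameter set used throughout: the 120 mM perchlorate condition
# (k1 = 0.03 h^-1, k2 = 0.13 mM^-1 h^-1, A0 = 2 mM).
p120 <- fw_params(0.03, 0.13, 2)

test_that("fw_params validates and derives r, K and the degenerate flag", {
  expect_equal(p120$r, 0.03 + 0.13 * 2)
  expect_equal(p120$K, 2 + 0.03 / 0.13)
  expect_false(p120$degenerate)
  expect_true(fw_params(0.5, 0.1, 2)$degenerate) # k1 >= k2*A0
  expect_error(fw_params(0, 0.1, 2), "k1")
  expect_error(fw_params(0.1, -1, 2), "k2")
  expect_error(fw_params(0.1, 0.1, 0), "A0")
})

test_that("fw_monomer satisfies the initial condition and limits", {
  expect_equal(fw_monomer(p120, 0), 2)
  g <- fw_param_grid()
  for (i in seq_len(nrow(g))) {
    p <- fw_params(g$k1[i], g$k2[i], g$A0[i])
    expect_equal(fw_monomer(p, 0), g$A0[i], tolerance = 1e-12)
    ts <- seq(0, 48, length.out = 25)
    a <- fw_monomer(p, ts)
    expect_true(all(diff(a) < 0))                       # strictly decreasing
    expect_equal(fw_aggregate(p, ts), g$A0[i] - a,      # conservation
                 tolerance = 1e-12)
  }
  expect_lt(fw_monomer(fw_params(0.01, 0.11, 2), 48), 1e-3) # full conversion
  expect_error(fw_monomer(p120, -1), "t must be")
})

test_that("closed-form monomer matches adaptive ODE integration on the grid", {
  g <- fw_param_grid()
  ts <- seq(0, 30, length.out = 11)
  for (i in seq_len(nrow(g))) {
    analytic <- fw_monomer(fw_params(g$k1[i], g$k2[i], g$A0[i]), ts)
    numeric <- ode_fw_monomer(g$k1[i], g$k2[i], g$A0[i], ts)
    expect_lt(max(abs(analytic - numeric)), 1e-6)
  }
})

test_that("fw_tmax matches the argmax of the numerically differentiated curve", {
  for (p in list(p120, fw_params(0.01, 0.115, 2))) {
    tm <- fw_tmax(p)
    # golden-section maximize of the finite-difference growth rate
    rate <- function(t) (fw_monomer(p, t) - fw_monomer(p, t + 1e-5)) / 1e-5
    opt <- optimize(rate, c(0, 40), maximum = TRUE, tol = 1e-9)
    expect_equal(as.numeric(tm), opt$maximum, tolerance = 1e-4)
  }
  expect_equal(as.numeric(fw_tmax(p120)), log(0.26 / 0.03) / 0.29,
               tolerance = 1e-12)
  # k1 == k2*A0: log(1) = 0
  expect_warning(tm <- fw_tmax(fw_params(0.2, 0.1, 2)), "degenerate")
  expect_equal(as.numeric(tm), 0)
  expect_true(attr(tm, "degenerate"))
})

test_that("analytic jerk times: symmetry is exact and values match root-finding", {
  ph <- fw_jerk_times(p120)
  # logistic symmetry, exact up to floating-point representation
  expect_equal(ph$tmax - ph$t1, ph$t2 - ph$tmax, tolerance = 1e-14)
  expect_equal(ph$offset, log(2 + sqrt(3)) / 0.29, tolerance = 1e-12)
  g <- fw_param_grid()
  for (i in seq_len(nrow(g))) {
    p <- fw_params(g$k1[i], g$k2[i], g$A0[i])
    a <- suppressWarnings(fw_jerk_times(p))
    n <- fw_jerk_times_numeric(p)
    expect_lt(abs(a$t1 - n$t1), 1e-5)
    expect_lt(abs(a$t2 - n$t2), 1e-5)
    expect_lt(abs(a$tmax - n$tmax), 1e-5)
    expect_equal(a$tmax, (a$t1 + a$t2) / 2, tolerance = 1e-12)
    expect_equal(n$tmax, (n$t1 + n$t2) / 2, tolerance = 1e-5)
  }
})

test_that("numeric jerk oracle is grid-converged and flags degenerate regimes", {
  n1 <- fw_jerk_times_numeric(p120, n_grid = 1024L)
  n2 <- fw_jerk_times_numeric(p120, n_grid = 2048L)
  expect_lt(abs(n1$t1 - n2$t1), 1e-7)
  expect_lt(abs(n1$t2 - n2$t2), 1e-7)
  expect_error(fw_jerk_times(fw_params(0.5, 0.1, 2)), "degenerate")
  expect_error(fw_jerk_times_numeric(fw_params(0.5, 0.1, 2)),
               "degenerate|bracket")
})

test_that("fw_max_rate equals r*K/4 and the sampled maximum of dB/dt", {
  expect_equal(fw_max_rate(p120), 0.29 * (2 + 0.03 / 0.13) / 4,
               tolerance = 1e-12)
  ts <- seq(0, 30, by = 0.01)
  db <- diff(fw_aggregate(p120, ts)) / diff(ts)
  expect_gte(fw_max_rate(p120) + 1e-6, max(db))
  expect_equal(fw_max_rate(p120), max(db), tolerance = 1e-3)
  # k1 -> 0 limit: max rate -> k2*A0^2/4, so doubling A0 quadruples it
  lim <- function(A0) fw_max_rate(fw_params(1e-9, 0.13, A0))
  expect_equal(lim(4) / lim(2), 4, tolerance = 1e-6)
})

test_that("fit_fw recovers noise-free generating parameters to 1e-4 relative", {
  tr <- gen_fw_trace(p120, seq(0, 24, length.out = 49), noise_spec(0))
  fit <- fit_fw(tr)
  expect_lt(abs(fit$params$k1 - 0.03) / 0.03, 1e-4)
  expect_lt(abs(fit$params$k2 - 0.13) / 0.13, 1e-4)
  expect_identical(fit$quality, "good")
  expect_gt(fit$r_squared, 0.9999)
  # phase recomputed from the fitted params satisfies the invariants
  expect_true(fit$phase$t1 < fit$phase$tmax && fit$phase$tmax < fit$phase$t2)
  # determinism: identical trace in, identical fit out
  fit2 <- fit_fw(tr)
  expect_identical(fit$params$k1, fit2$params$k1)
  expect_identical(fit$params$k2, fit2$params$k2)
})

test_that("fit_fw recovers parameters across the grid (noise-free)", {
  g <- fw_param_grid()
  for (i in seq_len(nrow(g))) {
    p <- fw_params(g$k1[i], g$k2[i], g$A0[i])
    tr <- gen_fw_trace(p, seq(0, 48, length.out = 49), noise_spec(0))
    fit <- fit_fw(tr, A0 = g$A0[i])
    expect_lt(abs(fit$params$k1 - g$k1[i]) / g$k1[i], 1e-4)
    expect_lt(abs(fit$params$k2 - g$k2[i]) / g$k2[i], 1e-4)
  }
})

test_that("fit_fw flags a flat trace as poor instead of crashing", {
  flat <- aggregation_trace(seq(0, 24, length.out = 25), rep(2, 25),
                            metadata = list(A0 = 2))
  fit <- fit_fw(flat)
  expect_identical(fit$quality, "poor")
  expect_false(is.na(fit$diagnostic))
})

test_that("fit_fw validates inputs", {
  expect_error(fit_fw(list(times = 1:3, monomer = c(2, 1, 0))), ">= 6")
  tr <- list(times = seq(0, 10, by = 2), monomer = c(3, 2, 1.5, 1, 0.5, 0.2),
             metadata = list(A0 = 2))
  expect_error(fit_fw(tr), "outside")
})

test_that("fit_amplitude handles traces that plateau above zero monomer", {
  # incomplete conversion: the whole curve scaled by 0.8
  ts <- seq(0, 24, length.out = 49)
  tr <- aggregation_trace(ts, 0.8 * fw_monomer(p120, ts),
                          metadata = list(A0 = 2))
  fit <- fit_fw(tr, fit_amplitude = TRUE)
  expect_identical(fit$quality, "good")
  expect_lt(abs(fit$params$k1 - 0.03) / 0.03, 1e-3)
  expect_lt(abs(fit$params$k2 - 0.13) / 0.13, 1e-3)
})
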