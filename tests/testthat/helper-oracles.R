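# Independent numerical oracles used to cross-check the closed-form kinetics.
# These deliberately avoid every analytic expression in the package: the ODE
# is integrated numerically, derivatives are taken by finite differences.

# Adaptive Cash-Karp RK45 integrator for a scalar ODE dy/dt = f(t, y).
# Returns y at each requested time (times sorted ascending, times[1] = t0).
ode_rk45 <- function(f, y0, times, atol = 1e-10, rtol = 1e-10) {
  # Cash-Karp coefficients
  a <- list(c(), c(1/5), c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  cs <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  step <- function(t, y, h) {
    k <- numeric(6)
    k[1] <- f(t, y)
    for (i in 2:6) {
      k[i] <- f(t + cs[i] * h, y + h * sum(a[[i]] * k[seq_len(i - 1)]))
    }
    y5 <- y + h * sum(c5 * k)
    y4 <- y + h * sum(c4 * k)
    list(y = y5, err = abs(y5 - y4))
  }
  out <- numeric(length(times))
  out[1] <- y0
  t <- times[1]; y <- y0
  h <- diff(range(times)) / 100
  for (j in 2:length(times)) {
    tend <- times[j]
    while (t < tend - 1e-14) {
      h <- min(h, tend - t)
      s <- step(t, y, h)
      tol <- atol + rtol * abs(y)
      if (s$err <= tol) {
        t <- t + h; y <- s$y
        h <- h * min(5, max(0.2, 0.9 * (tol / max(s$err, 1e-300))^0.2))
      } else {
        h <- h * max(0.2, 0.9 * (tol / s$err)^0.25)
      }
    }
    out[j] <- y
  }
  out
}

# Monomer loss by numeric integration of dA/dt = -k1*A - k2*A*(A0 - A).
ode_fw_monomer <- function(k1, k2, A0, times) {
  f <- function(t, A) -k1 * A - k2 * A * (A0 - A)
  o <- order(times)
  ts <- times[o]
  prepend <- ts[1] > 0
  if (prepend) ts <- c(0, ts)
  y <- ode_rk45(f, A0, ts)
  if (prepend) y <- y[-1]
  y[order(o)]
}

# 3x3x3 grid spanning the fitted parameter ranges of the perchlorate series
# (k1 0.01-0.03 h^-1, k2 0.11-0.13 mM^-1 h^-1) around the experimental
# A0 = 2 mM. All 27 points are non-degenerate with t1 > 0.
fw_param_grid <- function() {
  expand.grid(k1 = c(0.01, 0.02, 0.03),
              k2 = c(0.11, 0.12, 0.13),
              A0 = c(1.5, 2, 2.5))
}
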