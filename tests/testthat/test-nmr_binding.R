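concs12 <- seq(0, 0.5, length.out = 12)

test_that("isotherm_shift: limits, monotonicity, half-saturation", {
  expect_equal(isotherm_shift(5, 8.3, -0.15, 0), 8.3)
  expect_equal(isotherm_shift(0, 8.3, -0.15, c(0, 0.1, 0.5)), rep(8.3, 3))
  # Ka = 6, c = 1/6: Ka*c = 1, half-saturation
  expect_equal(isotherm_shift(6, 8.3, -0.15, 1 / 6), 8.3 - 0.15 / 2,
               tolerance = 1e-12)
  y <- isotherm_shift(5, 8.3, -0.15, seq(0, 2, by = 0.1))
  expect_true(all(diff(y) < 0))                  # monotone (delta_max < 0)
  expect_true(all(y >= 8.3 - 0.15))              # bounded by saturation
  expect_error(isotherm_shift(-1, 8.3, -0.15, 0.1), "Ka")
  expect_error(isotherm_shift(5, 8.3, -0.15, -0.1), "conc")
})

test_that("exact quadratic isotherm approaches the excess-ligand form", {
  # 5 mM peptide, >= 90-fold salt excess: forms agree closely
  cs <- seq(0.05, 0.5, by = 0.05)
  approx <- isotherm_shift(6, 8.3, -0.15, cs)
  exact <- isotherm_shift_exact(6, 8.3, -0.15, cs, P0 = 0.005)
  expect_lt(max(abs(approx - exact)), 2e-3)
  expect_equal(isotherm_shift_exact(0, 8.3, -0.15, cs, P0 = 0.005),
               rep(8.3, length(cs)))
})

test_that("fit_ka recovers noiseless parameters at the reported extremes", {
  for (ka in c(2, 6, 7)) {
    s <- gen_titration(ka, 8.30, -0.15, concs12, noise_spec(0))
    f <- fit_ka(s)
    expect_lt(abs(f$Ka - ka) / ka, 1e-4)
    expect_equal(f$delta_free, 8.30, tolerance = 1e-6)
    expect_equal(f$delta_max, -0.15, tolerance = 1e-4)
    expect_gt(f$r_squared, 0.99999)
  }
})

test_that("fit_ka recovers (Ka, delta_max) when saturation is approached", {
  # property: max(Ka*conc) >= 1 across a range of Ka and delta_max
  cases <- expand.grid(ka = c(2, 5, 10, 30), dm = c(-0.3, -0.05, 0.2))
  for (i in seq_len(nrow(cases))) {
    s <- gen_titration(cases$ka[i], 8.1, cases$dm[i], concs12, noise_spec(0))
    f <- fit_ka(s)
    expect_lt(abs(f$Ka - cases$ka[i]) / cases$ka[i], 1e-4)
    expect_lt(abs(f$delta_max - cases$dm[i]) / abs(cases$dm[i]), 1e-4)
  }
})

test_that("fit_ka warns on weak binding and on flat series", {
  s <- gen_titration(0.1, 8.3, -0.15, concs12, noise_spec(0))
  f <- fit_ka(s)
  expect_match(f$warning, "weak binding")
  flat <- titration_series(concs12, rep(8.3, 12))
  ff <- fit_ka(flat)
  expect_equal(ff$Ka, 0)
  expect_match(ff$warning, "flat")
})

test_that("fit_ka is accurate under realistic shift noise (200 replicates)", {
  errs <- vapply(1:200, function(s) {
    f <- fit_ka(gen_titration(5, 8.30, -0.15, concs12,
                              noise_spec(0.002, seed = 3000L + s)))
    abs(f$Ka - 5) / 5
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("titration_series validates its invariants", {
  expect_error(titration_series(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(8, 5)),
               "first concentration")
  expect_error(titration_series(c(0, 0.1, 0.1, 0.3, 0.4), rep(8, 5)),
               "strictly increasing")
  expect_error(titration_series(c(0, 0.1, 0.2), rep(8, 3)), ">= 5")
})

# ---- CSP --------------------------------------------------------------------

mk_table <- function(shifts, positions = 2:15, peptide = "1", salt = NA) {
  shift_table(positions, shifts, peptide = peptide,
              condition = list(salt = salt))
}

test_that("csp is zero/insignificant on identical tables and antisymmetric", {
  base <- 8 + (2:15) / 100
  free <- mk_table(base)
  expect_true(all(csp(free, free)$delta$delta_ppm == 0))
  expect_true(all(!csp(free, free)$delta$significant))
  bound <- mk_table(base + seq(-0.1, 0.1, length.out = 14), salt = "NaClO4")
  ab <- csp(free, bound)$delta$delta_ppm
  ba <- csp(bound, free)$delta$delta_ppm
  expect_equal(ab, -ba, tolerance = 1e-15)
})

test_that("csp classifies signs and applies the 0.005 ppm error bubble", {
  free <- mk_table(rep(8.3, 14))
  d <- rep(0, 14); d[1] <- -0.006; d[2] <- 0.006; d[3] <- -0.004; d[4] <- 0.004
  m <- csp(free, mk_table(8.3 + d))
  expect_identical(m$delta$class[1], "association")     # upfield
  expect_identical(m$delta$class[2], "non-specific")    # downfield
  expect_true(m$delta$significant[1] && m$delta$significant[2])
  expect_false(m$delta$significant[3] || m$delta$significant[4])
})

test_that("the largest-magnitude perturbation is identifiable (K12 case)", {
  p1 <- builtin_peptide("1")
  base <- 8 + (2:15) / 100
  d <- rep(-0.02, 14)
  d[which(2:15 == 12)] <- -0.136   # K12 upon NaClO4
  m <- csp(mk_table(base), mk_table(base + d, salt = "NaClO4"))
  imax <- which.max(abs(m$delta$delta_ppm))
  expect_identical(residue_label(p1, m$delta$position[imax]), "K12")
  expect_equal(abs(m$delta$delta_ppm[imax]), 0.136)
})

test_that("csp rejects coverage mismatches, listing the missing positions", {
  expect_error(csp(mk_table(rep(8.3, 14)), mk_table(rep(8.3, 13), positions = 2:14)),
               "coverage mismatch.*15")
})

test_that("neighbor_asymmetry counts holds, exceptions (ties) and skips", {
  base <- rep(8.3, 14)
  d <- rep(-0.01, 14)
  names(d) <- 2:15
  d[c("6", "10", "12")] <- -0.05   # N-H_i larger than N-H_{i+1} everywhere
  m <- csp(mk_table(base), mk_table(base + d))
  rep1 <- neighbor_asymmetry(m, c(6, 10, 12))
  expect_equal(rep1$summary$n_holds, 3)
  expect_equal(rep1$summary$n_exceptions, 0)
  # tie at position 10: |d_10| == |d_11| -> exception under strict inequality
  d2 <- d; d2["11"] <- d2["10"]
  rep2 <- neighbor_asymmetry(csp(mk_table(base), mk_table(base + d2)), c(6, 10, 12))
  expect_equal(rep2$summary$n_exceptions, 1)
  expect_false(rep2$comparisons$holds[rep2$comparisons$position == 10])
  # position 15 has no observable i+1 -> skipped with note
  rep3 <- neighbor_asymmetry(m, c(6, 15))
  expect_equal(rep3$summary$skipped, 15L)
  # the aggregate bookkeeping can represent counts like {35, 1}
  expect_identical(rep2$summary$n_holds + rep2$summary$n_exceptions, 3L)
})

test_that("bubble map export: area (not radius) proportional to |delta|", {
  base <- rep(8.3, 14)
  d <- seq(-0.1, 0.03, length.out = 14)
  m <- csp(mk_table(base), mk_table(base + d))
  tab <- bubble_map_export(m, peptide = builtin_peptide("1"))
  expect_equal(tab$area, abs(d))
  expect_equal(tab$radius, sqrt(abs(d) / pi))
  # doubling |delta| doubles the area, radius grows by sqrt(2)
  m2 <- csp(mk_table(base), mk_table(base + 2 * d))
  tab2 <- bubble_map_export(m2)
  expect_equal(tab2$area, 2 * tab$area)
  expect_equal(tab2$radius, sqrt(2) * tab$radius)
  expect_identical(tab$color_class, ifelse(d < 0, "up", ifelse(d > 0, "down", "zero")))
  # zero map: all areas zero
  z <- bubble_map_export(csp(mk_table(base), mk_table(base)))
  expect_true(all(z$area == 0) && all(z$color_class == "zero"))
})

test_that("equivalents convert at the 5 mM peptide concentration", {
  expect_equal(equivalents_to_molar(93), 0.465)
})
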