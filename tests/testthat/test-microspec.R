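geom <- domain_geometry()  # r_d = 0.282 um, y0 = 93.4 keV/um

test_that("sphere chord sampling matches the mu-randomness distribution", {
  l <- chord_pdf_sample(0.282, 2e5, seed = 42)
  expect_true(all(l >= 0 & l <= 2 * 0.282))
  # Cauchy mean chord 4r/3
  expect_equal(mean(l), 4 * 0.282 / 3, tolerance = 2e-3)
  # analytic CDF F(l) = l^2 / (4 r^2): at l = r it is 1/4
  expect_equal(mean(l <= 0.282), 0.25, tolerance = 0.01)
  expect_error(chord_pdf_sample(-1, 10, seed = 1))
  expect_identical(chord_pdf_sample(0.282, 100, seed = 5),
                   chord_pdf_sample(0.282, 100, seed = 5))
})

test_that("stopping-power interpolation honors the table", {
  # interpolation at a tabulated point returns the tabulated value
  expect_equal(stopping_power("alpha", 5), 91, tolerance = 1e-9)
  expect_equal(stopping_power("electron", 0.1), 0.412, tolerance = 1e-9)
  # above the Bragg peak LET decreases with energy
  expect_gt(stopping_power("alpha", 0.7), stopping_power("alpha", 7))
  # electrons are sparsely ionizing compared with alphas
  expect_lt(stopping_power("electron", 0.25),
            stopping_power("alpha", 6) / 100)
  expect_error(stopping_power("alpha", 100), "out of tabulated range")
})

test_that("every sampled spectrum is normalized and reproducible", {
  for (case in list(list("At-211", "alpha"), list("At-211", "beta"),
                    list("F-18", "beta"), list("Lu-177", "beta"))) {
    s <- compute_dose_pd(load_nuclide(case[[1]]), case[[2]], geom,
                         n_samples = 2e4, seed = 3)
    expect_equal(sum(s$density * diff(s$y_edges)), 1, tolerance = 1e-6,
                 label = paste(case[[1]], case[[2]]))
  }
  s1 <- compute_dose_pd(load_nuclide("F-18"), "beta", geom, 1e4, seed = 9)
  s2 <- compute_dose_pd(load_nuclide("F-18"), "beta", geom, 1e4, seed = 9)
  expect_identical(s1$density, s2$density)
  expect_error(compute_dose_pd(load_nuclide("F-18"), "alpha", geom, 1e3,
                               seed = 1), "no alpha-component emissions")
})

test_that("constant-LET track reproduces the closed-form chord transform", {
  # For constant LET L with track length >> 2 r_d, the dose-weighted
  # lineal-energy density is d(y) ~ y^2 on [0, 1.5 L] (chord pdf ~ l,
  # dose weight ~ l), so the dose-mean y is (3/4) * 1.5 L = 1.125 L.
  L <- 100
  src <- mono_nuclide("alpha", 10)
  s <- compute_dose_pd(src, "alpha", geom, n_samples = 2e5, seed = 21,
                       let_fun = function(p, e) rep(L, length(e)))
  expect_equal(dose_mean_y(s), 1.125 * L, tolerance = 0.02)
  # support bound: y <= 2 r_d L / (4 r_d / 3) = 1.5 L
  expect_lt(max(s$y_mid[s$density > 0]), 1.5 * L * 1.05)
})

test_that("At-211 alpha and F-18 beta spectra occupy the expected y ranges", {
  sa <- compute_dose_pd(load_nuclide("At-211"), "alpha", geom, 5e4, seed = 2)
  sf <- compute_dose_pd(load_nuclide("F-18"), "beta", geom, 5e4, seed = 2)
  frac_in <- function(s, lo, hi) {
    sel <- s$y_mid >= lo & s$y_mid <= hi
    sum(s$density[sel] * diff(s$y_edges)[sel])
  }
  # alpha dose concentrated at high lineal energy, beta at low
  expect_gt(frac_in(sa, 40, 1000), 0.8)
  expect_gt(frac_in(sf, 0, 15), 0.9)
  expect_gt(dose_mean_y(sa), 10 * dose_mean_y(sf))
})

test_that("y* saturation has the closed-form and limiting behaviour", {
  # single-bin spectrum centered exactly at y0
  y0 <- 93.4
  edges <- c(y0 / 1.01, y0 * 1.01)
  edges <- c(y0^2 / edges[2], edges[2])  # geometric midpoint exactly y0
  spec1 <- lineal_spectrum(edges, 1 / diff(edges))
  expect_equal(y_star(spec1, y0), y0 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(y_star(spec1, y0), 59.04, tolerance = 1e-3)

  s <- compute_dose_pd(load_nuclide("At-211"), "alpha", geom, 5e4, seed = 4)
  # y0 -> Inf recovers the dose-mean lineal energy
  expect_equal(y_star(s, 1e6), dose_mean_y(s), tolerance = 1e-3)
  # saturation only reduces; monotone nondecreasing in y0
  ys <- vapply(c(20, 50, 93.4, 200, 1e3, 1e6), function(y0) y_star(s, y0),
               numeric(1))
  expect_true(all(diff(ys) > 0))
  expect_true(all(ys <= dose_mean_y(s) * (1 + 1e-9)))
})

test_that("z*_1D conversion follows the specific-energy dimensional identity", {
  edges <- c(0.99, 1 / 0.99)  # geometric midpoint exactly 1 keV/um
  spec <- lineal_spectrum(edges, 1 / diff(edges))
  z <- z_star_1d(spec, domain_geometry(r_d = 0.282, y0 = 1e9))
  expect_equal(z, 0.6411, tolerance = 1e-3)  # 0.1602/(pi 0.282^2)
  expect_gte(z, 0)
  z2 <- z_star_1d(spec, domain_geometry(r_d = 0.564, y0 = 1e9))
  expect_equal(z / z2, 4, tolerance = 1e-9)
})

test_that("spectrum mixing is the dose-weighted average", {
  sa <- compute_dose_pd(load_nuclide("At-211"), "alpha", geom, 2e4, seed = 5)
  sb <- compute_dose_pd(load_nuclide("At-211"), "beta", geom, 2e4, seed = 6)
  expect_equal(mix_spectra(sa, sb, 1, 0)$density, sa$density)
  expect_equal(mix_spectra(sa, sa, 1, 1)$density, sa$density)
  expect_error(mix_spectra(sa, sb, 0, 0), "degenerate")

  # disjoint-support construction: 3:1 dose split leaves 75% of the dose
  # weight on the alpha support
  e <- c(1, 2, 4, 8)
  d1 <- lineal_spectrum(e, c(1, 0, 0) / 1)
  d2 <- lineal_spectrum(e, c(0, 0, 1) / 4)
  mx <- mix_spectra(d1, d2, 3, 1)
  expect_equal(mx$density[1] * 1, 0.75)
  expect_equal(mx$density[3] * 4, 0.25)

  # mixing then saturating equals saturating the mixed integrand
  z_mix <- z_star_1d(mix_spectra(sa, sb, 2, 1), geom)
  z_comb <- (2 * z_star_1d(sa, geom) + 1 * z_star_1d(sb, geom)) / 3
  expect_equal(z_mix, z_comb, tolerance = 1e-9)
})

test_that("spectra round-trip through the CSV + sidecar serialization", {
  s <- compute_dose_pd(load_nuclide("F-18"), "beta", geom, 1e4, seed = 8)
  path <- file.path(tempdir(), "spec_f18.csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$density, s$density)
  expect_equal(s2$y_edges, s$y_edges)
  expect_equal(s2$seed, s$seed)
})
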