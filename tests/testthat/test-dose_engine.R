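test_that("local dose reproduces the per-decay energy bookkeeping", {
  ph <- tiny_water_phantom(c(4, 4, 4), 4)  # 6.4e-5 kg voxels
  decays <- array(0, c(4, 4, 4)); decays[2, 2, 2] <- 1e6
  D <- local_dose(decays, 6.8, ph)
  # hand arithmetic with the package energy constant
  expect_equal(D[2, 2, 2], 1e6 * 6.8 * 1.602176634e-13 / 6.4e-5,
               tolerance = 1e-12)
  expect_equal(D[2, 2, 2], 1.702e-2, tolerance = 1e-3)
  expect_equal(sum(D > 0), 1)
  # additive over emission lines
  expect_equal(local_dose(decays, 3.4, ph) + local_dose(decays, 3.4, ph),
               D, tolerance = 1e-12)
  expect_error(local_dose(decays[1:2, , ], 6.8, ph))
})

test_that("photon kernel conserves energy and decays beyond the source", {
  d <- c(16, 16, 16)
  k <- photon_kernel(0.511, 1.0, 4, d)
  esc <- attr(k, "escaped_fraction")
  expect_equal(sum(k) + esc, 1, tolerance = 1e-6)
  expect_true(esc >= 0 && esc < 1)
  # monotone decrease along an axis beyond the first voxel
  prof <- k[16:31, 16, 16]
  expect_true(all(diff(prof[-1]) < 0))
  # analytic radial cdf integrates to 1 over an infinite medium
  mu <- attr(k, "mu_cm"); kk <- tatdose:::.buildup_coeff(0.511)
  g <- function(r) mu * exp(-mu * r) * (1 + kk * mu * r) / (1 + kk)
  expect_equal(integrate(g, 0, Inf)$value, 1, tolerance = 1e-8)
  # the buildup pushes the half-value radius beyond the attenuation-only
  # ln2/mu, but by less than a factor of two at this energy
  Fc <- function(r) 1 - exp(-mu * r) * (1 + kk + kk * mu * r) / (1 + kk)
  r50 <- uniroot(function(r) Fc(r) - 0.5, c(1e-3, 100))$root
  expect_gt(r50, log(2) / mu)
  expect_lt(r50, 2 * log(2) / mu)
  expect_error(photon_kernel(10, 1, 4, d), "out of tabulated range")
})

test_that("photon dose maps are linear, blurred versions of the source", {
  d <- c(16, 16, 16)
  ph <- build_phantom(array(0, d), 4)
  decays <- array(0, d); decays[8, 8, 8] <- 1e7
  lines <- data.frame(energy_mev = 0.511, yield = 2)
  D1 <- photon_dose_map(decays, lines, ph)
  # energy balance: deposited = emitted * (1 - escaped)
  edep <- sum(D1 * ph$mass_kg) / 1.602176634e-13
  emitted <- 1e7 * 2 * 0.511
  expect_equal(edep, emitted * (1 - attr(D1, "escaped_fraction")),
               tolerance = 1e-6)
  # FFT convolution against a direct kernel-sum oracle on the grid
  kern <- photon_kernel(0.511, 1.0, 4, d)
  ai <- arrayInd(seq_len(prod(d)), d)
  off <- sweep(ai, 2, c(8, 8, 8))           # offsets from the source voxel
  kv <- kern[cbind(off[, 1] + d[1], off[, 2] + d[2], off[, 3] + d[3])]
  direct <- 1e7 * 2 * 0.511 * kv            # MeV per voxel, by hand
  expect_equal(as.vector(D1 * ph$mass_kg / 1.602176634e-13),
               direct, tolerance = 1e-8)
  # exact linearity in activity
  D2 <- photon_dose_map(2 * decays, lines, ph)
  expect_equal(as.vector(D2), 2 * as.vector(D1), tolerance = 1e-12)
  # spatial spread exceeds the point source's
  w <- as.vector(D1) / sum(D1)
  ai <- arrayInd(seq_len(prod(d)), d)
  var_dose <- sum(w * rowSums((ai - 8)^2))
  expect_gt(var_dose, 1)
})

test_that("the MC oracle is reproducible and exact for pure alpha emitters", {
  d <- c(8, 8, 8)
  ph <- build_phantom(array(0, d), 4)
  decays <- array(1e4, d)
  src <- mono_nuclide("alpha", 6)
  o1 <- mc_oracle(decays, ph, src, n_histories = 1e3, seed = 5)
  expect_equal(o1$D_alpha, local_dose(decays, 6, ph), tolerance = 1e-12)
  expect_equal(as.vector(o1$D_beta), rep(0, prod(d)))
  g <- mono_nuclide("photon", 0.511)
  o2 <- mc_oracle(decays, ph, g, n_histories = 5e3, seed = 9)
  o3 <- mc_oracle(decays, ph, g, n_histories = 5e3, seed = 9)
  expect_identical(o2$D_beta, o3$D_beta)
  expect_gt(o2$escaped_fraction, 0)
})

test_that("full dose maps split components per the tally convention", {
  d <- c(12, 12, 12)
  ph <- build_phantom(array(0, d), 4)
  cum <- array(0, d); cum[6, 6, 6] <- 1e4  # Bq h
  at <- compute_dose_maps(cum, load_nuclide("At-211"), ph)
  # alpha dominates in the source voxel and is strictly local
  expect_gt(at$D_alpha[6, 6, 6] / at$D_beta[6, 6, 6], 10)
  expect_equal(sum(at$D_alpha > 0), 1)
  f18 <- compute_dose_maps(cum, load_nuclide("F-18"), ph)
  expect_equal(max(f18$D_alpha), 0)
  # photon transport reaches voxels with zero activity
  expect_gt(f18$D_beta[1, 1, 1], 0)
  # deposited energy consistent with doses and masses, and bounded by the
  # emitted energy
  expect_equal(f18$E_dep,
               (f18$D_alpha + f18$D_beta) * ph$mass_kg / 1.602176634e-13,
               tolerance = 1e-12)
  e_emit <- sum(per_decay_energy(load_nuclide("F-18"))) * 1e4 * 3600
  expect_lt(sum(f18$E_dep), e_emit)
  # linearity in injected activity
  f18b <- compute_dose_maps(2 * cum, load_nuclide("F-18"), ph)
  expect_equal(as.vector(f18b$D_total), 2 * as.vector(f18$D_total),
               tolerance = 1e-12)
})

test_that("optional beta-range blur spreads the electron dose", {
  d <- c(12, 12, 12)
  ph <- build_phantom(array(0, d), 4)
  cum <- array(0, d); cum[6, 6, 6] <- 1e4
  lu <- load_nuclide("Lu-177")
  d0 <- compute_dose_maps(cum, lu, ph)
  d1 <- compute_dose_maps(cum, lu, ph, beta_blur_sigma_mm = 2)
  expect_lt(d1$D_beta[6, 6, 6], d0$D_beta[6, 6, 6])
  expect_gt(d1$D_beta[6, 6, 5], d0$D_beta[6, 6, 5])
  # blur conserves the deposited electron energy
  expect_equal(sum(d1$D_beta * ph$mass_kg), sum(d0$D_beta * ph$mass_kg),
               tolerance = 1e-6)
})
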