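p <- hsg_params()  # alpha 0.251, beta 0.0615, mu 1.5, X 2, z*_ref fixed 1.0

test_that("recovery factor has the protracted-exposure limits and value", {
  expect_equal(recovery_factor(0.0961, 0, mu = 0), 1)
  expect_equal(recovery_factor(1e9, 0, mu = 1.5), 1, tolerance = 1e-8)
  # hand evaluation at lambda = 0.0961 /h, mu = 1.5 /h
  expect_equal(recovery_factor(0.0961, 0, mu = 1.5), 0.06021,
               tolerance = 1e-4)
  expect_error(recovery_factor(0, 0, mu = 1.5), "must be > 0")
  # accumulation (negative lambda_bio) is fine while the sum is positive
  expect_lt(recovery_factor(0.4, -0.2, 1.5), recovery_factor(0.4, 0, 1.5))
})

test_that("survival follows the saturation-corrected LQ form", {
  expect_equal(survival_fraction(0, 1, 1, p), 1)
  # reference radiation at the fraction size: alpha0 + beta z*_ref = alpha
  S <- survival_fraction(p$X, p$z_star_ref, 1, p)
  expect_equal(S, exp(-(0.251 * 2 + 0.0615 * 4)), tolerance = 1e-12)
  expect_equal(S, exp(-0.748), tolerance = 1e-12)
  # direct hand evaluation with alpha0 = 0.13
  p2 <- mkm_params(z_star_ref = (0.251 - 0.13) / 0.0615)
  expect_equal(survival_fraction(1, 36.4, 1, p2),
               exp(-(0.13 + 0.0615 * 36.4) * 1 - 0.0615), tolerance = 1e-12)
  expect_equal(survival_fraction(1, 36.4, 1, p2), 0.0880, tolerance = 1e-3)
})

test_that("eqdx inverts survival for the reference radiation", {
  expect_equal(eqdx(1, p), 0)
  expect_equal(eqdx(exp(-0.374), p), 1, tolerance = 1e-12)
  # a single reference fraction of size X maps to EQDX = X
  expect_equal(eqdx(survival_fraction(p$X, p$z_star_ref, 1, p), p), p$X,
               tolerance = 1e-9)
  # exact inverse across the clinical dose range for the reference
  # treatment PLAN, i.e. dose D delivered in fractions of size X with
  # per-fraction survival exp(-(alpha X + beta X^2))
  for (D in c(0.1, 0.5, 1, 2, 5, 10, 20)) {
    S_plan <- exp(-(p$alpha + p$beta * p$X) * D)
    expect_equal(eqdx(S_plan, p), D, tolerance = 1e-9)
  }
  # an acute single dose of reference radiation is more effective than the
  # fractionated plan above the fraction size and less effective below it
  expect_gt(eqdx(survival_fraction(5, p$z_star_ref, 1, p), p), 5)
  expect_lt(eqdx(survival_fraction(1, p$z_star_ref, 1, p), p), 1)
  expect_error(eqdx(1.5, p))
  expect_error(eqdx(0, p))
})

test_that("low-dose EQDX/dose ratio is linear in z* with the stated anchor", {
  # at z* = z*_ref the ratio is alpha / (alpha + beta X)
  expect_equal(rbe_limit_ratio(p$z_star_ref, p), 0.251 / 0.374,
               tolerance = 1e-9)
  expect_equal(rbe_limit_ratio(p$z_star_ref, p), 0.671, tolerance = 1e-3)
  zg <- seq(0, 50, by = 5)
  expect_true(all(diff(rbe_limit_ratio(zg, p)) > 0))
})

test_that("VOI survival is the mass-weighted mean and penalizes heterogeneity", {
  expect_equal(voi_survival(rep(0.3, 5), rep(2, 5)), 0.3)
  expect_equal(voi_survival(c(0.2, 0.4), c(1, 3)), 0.35)
  expect_equal(voi_survival(c(0.4, 0.2, 0.3), c(3, 2, 1)),
               voi_survival(c(0.2, 0.3, 0.4), c(2, 1, 3)))
  expect_error(voi_survival(numeric(0), numeric(0)), "empty")

  # two equal-mass voxels, 0 and 10 Gy of reference-quality radiation
  S <- survival_fraction(c(0, 10), p$z_star_ref, 1, p)
  sv <- voi_survival(S, c(1, 1))
  expect_equal(sv, (1 + exp(-8.66)) / 2, tolerance = 1e-6)
  ev <- eqdx(sv, p)
  expect_equal(ev, 1.853, tolerance = 1e-3)
  # far below the uniform-field EQDX at the same mean dose
  expect_lt(ev, eqdx(survival_fraction(5, p$z_star_ref, 1, p), p))
})

test_that("heterogeneous VOIs never beat the uniform field at equal mean dose", {
  # random two-voxel high-dose configurations, reference-quality radiation
  set.seed(77)
  for (i in 1:25) {
    m <- runif(2, 0.5, 2)
    D <- runif(2, 0, 12)
    dbar <- sum(D * m) / sum(m)
    if (dbar < 2) D <- D * 2.5 / max(dbar, 0.1)
    dbar <- sum(D * m) / sum(m)
    ev <- eqdx(voi_survival(survival_fraction(D, p$z_star_ref, 1, p), m), p)
    eu <- eqdx(survival_fraction(dbar, p$z_star_ref, 1, p), p)
    expect_lte(ev, eu * (1 + 1e-9))
  }
})

test_that("ignoring the dose-rate effect never decreases EQDX", {
  p0 <- mkm_params(mu = 1e-12, z_star_ref = 1.0)  # recovery switched off
  set.seed(12)
  for (i in 1:20) {
    D <- runif(1, 0, 20); zs <- runif(1, 0, 40)
    lam <- runif(1, 0.05, 2)
    G <- recovery_factor(lam, 0, p$mu)
    e_full <- eqdx(survival_fraction(D, zs, G, p), p)
    e_mu0 <- eqdx(survival_fraction(D, zs, recovery_factor(lam, 0, p0$mu),
                                    p0), p0)
    expect_gte(e_mu0, e_full - 1e-12)
  }
})

test_that("eqdx_map agrees with the scalar chain and handles edge voxels", {
  d <- c(4, 4, 2)
  Da <- array(0.3, d); Db <- array(0.1, d)
  za <- 30; zb <- 1.5
  em <- eqdx_map(Da, Db, za, zb, lambda_phy = 0.38, lambda_bio = 0.1, p = p)
  # uniform field equals the scalar pipeline
  zs <- (0.3 * za + 0.1 * zb) / 0.4
  G <- recovery_factor(0.38, 0.1, p$mu)
  e_scalar <- eqdx(survival_fraction(0.4, zs, G, p), p)
  expect_equal(as.vector(em$eqdx), rep(e_scalar, prod(d)), tolerance = 1e-12)

  # pure-beta voxel at z*_ref with G = 1 behaves like reference radiation
  em2 <- eqdx_map(array(0, 1), array(2, 1), NA, p$z_star_ref,
                  lambda_phy = 1e9, lambda_bio = 0, p = p)
  expect_equal(as.vector(em2$eqdx), 2, tolerance = 1e-6)

  # zero-dose voxels get EQDX 0
  Da[1] <- 0; Db[1] <- 0
  em3 <- eqdx_map(Da, Db, za, zb, 0.38, 0.1, p)
  expect_equal(em3$eqdx[1], 0)
  # doubling dose does not double EQDX (quadratic term)
  em4 <- eqdx_map(2 * Da, 2 * Db, za, zb, 0.38, 0.1, p)
  expect_gt(em4$eqdx[2], 2 * em3$eqdx[2])
  expect_error(eqdx_map(array(0, c(2, 2, 2)), array(0, c(3, 3, 3)),
                        za, zb, 0.38, 0, p))
})

test_that("dose-mass histogram is a mass-weighted survival curve of dose", {
  dmh1 <- dmh(rep(3, 10), rep(0.5, 10), edges = c(0, 1, 2, 2.999, 3.001))
  expect_equal(dmh1$mass_fraction, c(1, 1, 1, 1, 0))
  dose <- c(0, 1, 2, 4); mass <- c(1, 2, 3, 4)
  h <- dmh(dose, mass, edges = seq(0, 5, by = 0.001))
  expect_equal(h$mass_fraction[1], 1)
  expect_true(all(diff(h$mass_fraction) <= 0))
  # integral of the curve recovers the mass-weighted mean dose
  mean_from_dmh <- sum(h$mass_fraction[-1] * diff(h$dose))
  expect_equal(mean_from_dmh, sum(dose * mass) / sum(mass), tolerance = 1e-3)
})

test_that("parameter files round-trip and derive alpha0 on load", {
  path <- file.path(tempdir(), "mkm.json")
  write_mkm_params(p, path)
  p2 <- read_mkm_params(path)
  expect_equal(p2$alpha0, p$alpha0, tolerance = 1e-12)
  expect_equal(p2$geom$r_d, 0.282)
  expect_equal(p2$alpha_beta_ratio, 4.08, tolerance = 1e-3)
})
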