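test_that("single-patch growth rate is a - sigma^2/2", {
  expect_equal(r_single_patch(3, 7)$r, -0.5)
  expect_equal(r_single_patch(3, 6)$r, 0)
  expect_equal(r_single_patch(2, 0)$r, 2)
  expect_equal(r_single_patch(3, 7)$se, 0)
  expect_error(r_single_patch(1, -1))
})

test_that("method dispatch follows patch count and noise structure", {
  expect_equal(stochastic_growth_rate(generate_fixture("single_patch"))$method,
               "single_patch")
  expect_equal(stochastic_growth_rate(generate_fixture("two_patch_het",
                                                       rho = 0))$method,
               "quadrature_2p")
  expect_equal(stochastic_growth_rate(
    generate_fixture("equal_sigma_degenerate"))$method,
    "closedform_equal_sigma")
  m3 <- generate_fixture("symmetric_n", n = 3)
  expect_equal(stochastic_growth_rate(m3, T = 10, burn_in = 1,
                                      replicates = 2, seed = 1)$method,
               "mc_timeaverage")
  expect_error(stochastic_growth_rate(m3, method = "quadrature_2p"),
               "not applicable")
  expect_error(stochastic_growth_rate(generate_fixture("single_patch"),
                                      method = "closedform_equal_sigma"),
               "not applicable")
})

test_that("Monte Carlo average is exact when the integrand is constant", {
  # equal growth, one shared Brownian motion: f(y) = a - sigma^2/2 on all of
  # the simplex, so every replicate mean is identical
  sp <- two_patch_spec(a1 = 2, a2 = 2, d12 = 1, d21 = 1,
                       sigma1 = 1.5, sigma2 = 1.5, rho = 1)
  res <- r_mc_timeaverage(make_two_patch(sp), T = 5, burn_in = 1,
                          replicates = 3, dt = 1e-3, seed = 1)
  expect_equal(res$r, 2 - 1.5^2 / 2, tolerance = 1e-12)
  expect_equal(res$se, 0, tolerance = 1e-12)

  D <- matrix(c(-1, 1, 1, -1), 2)
  m0 <- patch_model(a = c(0, 0), competition = c(1, 1), D = D,
                    Gamma = matrix(0, 1, 2))
  res0 <- r_mc_timeaverage(m0, T = 5, burn_in = 1, replicates = 2,
                           dt = 1e-3, seed = 1)
  expect_equal(res0$r, 0, tolerance = 1e-15)
  expect_error(r_mc_timeaverage(m0, replicates = 1), "replicates")
})

test_that("stationary density: symmetry, normalization, moment ordering", {
  spsym <- two_patch_spec(a1 = 2, a2 = 2, d12 = 1, d21 = 1,
                          sigma1 = 1, sigma2 = 1, rho = 0)
  d <- stationary_density_2p(spsym)
  expect_equal(d$m1, 0.5, tolerance = 1e-8)
  xs <- seq(0.05, 0.45, by = 0.05)
  expect_equal(d$pdf(xs), d$pdf(1 - xs), tolerance = 1e-8)

  for (sp in list(het_spec(rho = 0), het_spec(rho = 0.5),
                  het_spec(rho = 1, sigma2 = 2))) {
    d <- stationary_density_2p(sp)
    expect_equal(stats::integrate(d$pdf, 0, 1, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    expect_true(0 <= d$m2 && d$m2 <= d$m1 && d$m1 <= 1)
  }
  expect_error(stationary_density_2p(
    two_patch_spec(a1 = 1, a2 = 1, d12 = 0, d21 = 0, sigma1 = 1,
                   sigma2 = 1)), "d12 > 0")
})

test_that("scale/speed density matches the independent-noise closed form", {
  # independent noise: exponents 2 sigma_i^2 / (sigma1^2 + sigma2^2) and
  # beta = 2 (a1 - a2 + d21 - d12) / (sigma1^2 + sigma2^2)
  sp <- two_patch_spec(a1 = 3, a2 = 4, d12 = 1.5, d21 = 0.7,
                       sigma1 = sqrt(7), sigma2 = 2, rho = 0)
  d <- stationary_density_2p(sp)
  expect_equal(d$branch, "nondegenerate")
  s1s <- 7; s2s <- 4; sc <- s1s + s2s
  beta <- 2 * (3 - 4 + 0.7 - 1.5) / sc
  expect_equal(unname(d$exponents["beta_exp"]), beta, tolerance = 1e-12)
  expect_equal(unname(d$exponents["alpha1"]), 2 * s1s / sc, tolerance = 1e-12)
  expect_equal(unname(d$exponents["alpha2"]), 2 * s2s / sc, tolerance = 1e-12)
  xs <- seq(0.01, 0.99, length.out = 199)
  printed <- (beta - 2 * s1s / sc) * log(xs) +
    (-beta - 2 * s2s / sc) * log(1 - xs) -
    (2 / sc) * (0.7 / xs + 1.5 / (1 - xs))
  got <- log(d$pdf(xs))
  expect_lt(max(abs((got - got[100]) - (printed - printed[100]))), 1e-8)
})

test_that("scale/speed density matches the shared-noise closed form", {
  # one Brownian motion, unequal volatilities: same shape with
  # scale (sigma1 - sigma2)^2; exponent constants 2 sigma1/(sigma1 - sigma2)
  # and -2 sigma2/(sigma1 - sigma2)
  s1 <- sqrt(7); s2 <- 2
  sp <- two_patch_spec(a1 = 3, a2 = 4, d12 = 1, d21 = 1,
                       sigma1 = s1, sigma2 = s2, rho = 1)
  d <- stationary_density_2p(sp)
  expect_equal(d$branch, "degenerate_unequal")
  sc <- (s1 - s2)^2
  expect_equal(d$scale, sc, tolerance = 1e-12)
  beta <- 2 * (3 - 4 + 1 - 1) / sc
  expect_equal(unname(d$exponents["beta_exp"]), beta, tolerance = 1e-12)
  expect_equal(unname(d$exponents["alpha1"]), 2 * s1 / (s1 - s2),
               tolerance = 1e-12)
  expect_equal(unname(d$exponents["alpha2"]), -2 * s2 / (s1 - s2),
               tolerance = 1e-12)
  xs <- seq(0.01, 0.99, length.out = 199)
  printed <- (beta - 2 * s1 / (s1 - s2)) * log(xs) +
    (-beta + 2 * s2 / (s1 - s2)) * log(1 - xs) -
    (2 / sc) * (1 / xs + 1 / (1 - xs))
  got <- log(d$pdf(xs))
  expect_lt(max(abs((got - got[100]) - (printed - printed[100]))), 1e-8)
})

test_that("beta exponent tracks the sign of a1 - a2 + d21 - d12", {
  for (pars in list(c(3, 4, 1, 1), c(4, 3, 1, 1), c(3, 4, 0.5, 2))) {
    sp0 <- two_patch_spec(a1 = pars[1], a2 = pars[2], d12 = pars[3],
                          d21 = pars[4], sigma1 = 1, sigma2 = 2, rho = 0)
    spd <- two_patch_spec(a1 = pars[1], a2 = pars[2], d12 = pars[3],
                          d21 = pars[4], sigma1 = 1, sigma2 = 2, rho = 1)
    num <- pars[1] - pars[2] + pars[4] - pars[3]
    b0 <- stationary_density_2p(sp0)$exponents["beta_exp"]
    bd <- stationary_density_2p(spd)$exponents["beta_exp"]
    expect_equal(unname(b0), 2 * num / 5, tolerance = 1e-12)
    expect_equal(unname(bd), 2 * num / 1, tolerance = 1e-12)
  }
})

test_that("quadrature growth rate agrees with Monte Carlo", {
  # nondegenerate, correlated, and degenerate-unequal branches, short runs
  for (sp in list(het_spec(rho = 0), het_spec(rho = 0.5),
                  het_spec(rho = 1, sigma2 = 2))) {
    rq <- r_quadrature_2p(sp)
    rmc <- r_mc_timeaverage(make_two_patch(sp), T = 200, burn_in = 20,
                            replicates = 6, dt = 1e-3, seed = 37)
    expect_lt(abs(rq$r - rmc$r), 3 * rmc$se)
  }
})

test_that("closed form under equal volatility and perfect correlation", {
  # equal growth rates: equilibrium exactly 1/2
  spe <- two_patch_spec(a1 = 2, a2 = 2, d12 = 0.7, d21 = 0.7,
                        sigma1 = 1, sigma2 = 1, rho = 1)
  expect_equal(r_closedform_equal_sigma(spe)$diagnostics$ystar, 0.5)

  sp <- het_spec(rho = 1, sigma2 = sqrt(7))
  res <- r_closedform_equal_sigma(sp)
  expect_equal(res$diagnostics$ystar, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(res$diagnostics$ystar, ystar_oracle(3, 4, 1, 1),
               tolerance = 1e-10)
  expect_equal(res$r, (5 + sqrt(5)) / 2 - 3.5, tolerance = 1e-12)

  # synchronization slice: r = a1 - d12 + d21 - sigma^2/2
  sps <- two_patch_spec(a1 = 2, a2 = 3, d12 = 1, d21 = 1.5,
                        sigma1 = 2, sigma2 = 2, rho = 1)
  expect_equal(r_closedform_equal_sigma(sps)$r, 2 - 1 + 1.5 - 2,
               tolerance = 1e-12)

  # asymmetric dispersal goes through the root finder
  spa <- two_patch_spec(a1 = 3, a2 = 4, d12 = 0.5, d21 = 2,
                        sigma1 = 1, sigma2 = 1, rho = 1)
  ys <- ystar_oracle(3, 4, 0.5, 2)
  expect_equal(r_closedform_equal_sigma(spa)$diagnostics$ystar, ys,
               tolerance = 1e-10)

  expect_error(r_closedform_equal_sigma(het_spec(rho = 0)),
               "not identically zero")
  expect_error(r_quadrature_2p(het_spec(rho = 1, sigma2 = sqrt(7))),
               "identically zero")
})

test_that("closed form agrees with Monte Carlo on the noiseless-proportion slice", {
  sp <- het_spec(rho = 1, sigma2 = sqrt(7))
  rc <- r_closedform_equal_sigma(sp)
  rmc <- r_mc_timeaverage(make_two_patch(sp), T = 100, burn_in = 20,
                          replicates = 4, dt = 1e-3, seed = 5)
  # proportion dynamics are deterministic: MC spread reflects burn-in only
  expect_lt(abs(rc$r - rmc$r), max(3 * rmc$se, 1e-3))
})

test_that("large-dispersal approximation and its limit", {
  sp <- het_spec(rho = 1, sigma2 = sqrt(7), alpha = 100)
  expect_equal(r_large_dispersal_approx(sp)$r, 0.00125, tolerance = 1e-12)
  # error against the exact closed form decays at least quadratically
  errs <- vapply(c(10, 20, 40, 80), function(al) {
    spl <- het_spec(rho = 1, sigma2 = sqrt(7), alpha = al)
    abs(r_large_dispersal_approx(spl)$r - r_closedform_equal_sigma(spl)$r)
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5))
  # limit value (a1 + a2)/2 - sigma^2/2 = 0 here
  expect_lt(abs(r_closedform_equal_sigma(
    het_spec(rho = 1, sigma2 = sqrt(7), alpha = 1e4))$r), 1e-3)
})

test_that("growth rate decreases with dispersal under shared noise", {
  rs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(al)
    r_closedform_equal_sigma(het_spec(rho = 1, sigma2 = sqrt(7),
                                      alpha = al))$r, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("growth rate is continuous in the model parameters", {
  base <- het_spec(rho = 0)
  r0 <- r_quadrature_2p(base)$r
  deltas <- c(0.1, 0.01, 0.001)
  gaps <- vapply(deltas, function(d) {
    sp <- two_patch_spec(a1 = 3 + d, a2 = 4 - d, d12 = 1 + d, d21 = 1 - d,
                         sigma1 = sqrt(7) + d, sigma2 = sqrt(7) - d, rho = 0)
    abs(r_quadrature_2p(sp)$r - r0)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.02)
})

test_that("stationary-density sampler reproduces its own density", {
  d <- stationary_density_2p(het_spec(rho = 0))
  x <- sample_stationary_2p(d, 1e5, seed = 4)
  cmp <- empirical_density_compare(x, d, bins = 50)
  expect_equal(cmp$type, "L1")
  expect_lt(cmp$value, 0.03)
  expect_equal(mean(x), d$m1, tolerance = 0.01)
})
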