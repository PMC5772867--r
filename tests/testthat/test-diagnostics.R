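test_that("persistence classification respects the indeterminate band", {
  expect_equal(classify_persistence(
    patchsde:::growth_rate_result(0.5, 0, "single_patch"))$verdict,
    "persistent")
  expect_equal(classify_persistence(
    patchsde:::growth_rate_result(-0.5, 0, "single_patch"))$verdict,
    "extinct")
  expect_equal(classify_persistence(
    patchsde:::growth_rate_result(0.01, 0.02, "mc_timeaverage"))$verdict,
    "inconclusive")
  # exactly on the closed-form boundary
  expect_equal(classify_persistence(r_single_patch(3, 6))$verdict,
               "inconclusive")
})

test_that("occupation fraction counts time near the boundary", {
  tm <- seq(0, 10, by = 0.1)
  const <- make_trajectory(tm, cbind(rep(1, length(tm)), rep(1, length(tm))))
  expect_equal(occupation_fraction(const, 0.5)$fraction, 0)

  half <- length(tm) %/% 2
  X <- cbind(c(rep(0.1, half), rep(1, length(tm) - half)), rep(1, length(tm)))
  tr <- make_trajectory(tm, X)
  expect_equal(occupation_fraction(tr, 0.5)$fraction, 0.5)

  # monotone in eta
  fr <- vapply(c(0.001, 0.01, 0.1, 0.5, 2), function(e)
    occupation_fraction(tr, e)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("occupation measure is additive over disjoint windows", {
  m <- generate_fixture("two_patch_het", rho = 0)
  tr <- simulate_X(m, c(1, 1), T = 20, dt = 1e-3, seed = 9, thin = 10)
  K <- nrow(tr$X) - 1
  sub <- function(idx) make_trajectory(tr$times[idx], tr$X[idx, , drop = FALSE])
  f_all <- occupation_fraction(tr, 0.5)$fraction
  i1 <- 1:(K / 2 + 1); i2 <- (K / 2 + 1):(K + 1)
  f1 <- occupation_fraction(sub(i1), 0.5)$fraction
  f2 <- occupation_fraction(sub(i2), 0.5)$fraction
  expect_equal(f_all, (f1 + f2) / 2, tolerance = 1e-12)
})

test_that("persistent dynamics rarely visit the extinction boundary", {
  m <- generate_fixture("two_patch_het", rho = 0)  # r > 0
  tr <- simulate_X(m, c(1, 1), T = 500, dt = 1e-3, seed = 2)
  expect_lte(occupation_fraction(tr, 0.01)$fraction, 0.05)
})

test_that("extinction slopes recover synthetic and theoretical decay rates", {
  tm <- seq(0, 10, by = 0.01)
  X <- cbind(exp(-0.3 * tm), exp(-0.3 * tm))
  sl <- extinction_slopes(make_trajectory(tm, X))
  expect_equal(unname(sl$slopes), c(-0.3, -0.3), tolerance = 1e-10)
  expect_equal(sl$spread, 0, tolerance = 1e-10)

  # distinct deterministic rates are not forced to agree
  X2 <- cbind(exp(-0.2 * tm), exp(-0.5 * tm))
  sl2 <- extinction_slopes(make_trajectory(tm, X2))
  expect_equal(sl2$spread, 0.3, tolerance = 1e-10)

  expect_error(extinction_slopes(make_trajectory(tm, X * 0)), "zero")
})

test_that("both patches decay at the closed-form rate in an extinct regime", {
  # equal growth rates, shared noise: r = 3 - 7/2 = -0.5
  sp <- two_patch_spec(a1 = 3, a2 = 3, d12 = 1, d21 = 1,
                       sigma1 = sqrt(7), sigma2 = sqrt(7), rho = 1)
  expect_equal(r_closedform_equal_sigma(sp)$r, -0.5)
  m <- make_two_patch(sp)
  # a single path's fitted slope carries O(sigma/sqrt(T)) sampling noise,
  # so the rate is recovered by averaging slopes across paths
  sl <- lapply(1:12, function(s)
    extinction_slopes(simulate_X(m, c(1, 1), T = 500, dt = 1e-3, seed = s)))
  mean_slopes <- rowMeans(vapply(sl, `[[`, numeric(2), "slopes"))
  expect_lt(max(abs(mean_slopes - (-0.5))), 0.1)
  # the two patches share the decay rate path by path
  expect_lt(max(vapply(sl, `[[`, numeric(1), "spread")), 0.05)
})

test_that("theta perturbations stay within their bound and shrink with theta", {
  base <- generate_fixture("two_patch_het", rho = 0)
  p0 <- make_theta_perturbation(base, 0, seed = 3)
  expect_equal(p0$model$a, base$a)
  expect_equal(p0$model$D, base$D)
  expect_equal(p0$model$Gamma, base$Gamma)

  for (theta in c(0.1, 0.05)) {
    p <- make_theta_perturbation(base, theta, seed = 3)
    expect_true(all(p$deviations <= theta))
    expect_true(validate_dispersal(p$model$D)$passed)
  }
  expect_error(make_theta_perturbation(base, 1.5, seed = 3), "smaller theta")

  r0 <- stochastic_growth_rate(base)$r
  gaps <- vapply(c(0.1, 0.05, 0.025), function(th) {
    p <- make_theta_perturbation(base, th, seed = 3)
    abs(stochastic_growth_rate(p$model)$r - r0)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("state-dependent perturbations respect the sup bound on a grid", {
  base <- generate_fixture("two_patch_het", rho = 0)
  p <- make_theta_perturbation(base, 0.1, mode = "state_dependent", seed = 5)
  for (x in list(c(0.1, 0.1), c(1, 1), c(10, 0.1), c(100, 100))) {
    expect_lt(max(abs(p$a_fun(x) - base$a)), 0.1)
    Dx <- p$D_fun(x)
    expect_lt(max(abs(Dx - base$D)), 0.1)
    expect_true(validate_dispersal(Dx)$passed)
    expect_lt(max(abs(p$Gamma_fun(x) - base$Gamma)), 0.1)
  }
})

test_that("abundances synchronize on the degenerate manifold slice", {
  sp <- attr(generate_fixture("synchronized_slice"), "spec")
  expect_equal(sp$a1 + 2 * (sp$d21 - sp$d12), sp$a2)

  eq <- synchronized_slice_check(sp, x0 = c(1, 1), T = 50, dt = 1e-3,
                                 seed = 21)
  expect_lte(eq$max_abs_diff, 1e-9)
  expect_equal(eq$r, 2 - 0.5 + 0.5 - 0.5)

  ne <- synchronized_slice_check(sp, x0 = c(2, 1), T = 50, dt = 1e-3,
                                 seed = 21)
  expect_true(ne$z_sign_constant)
  expect_true(ne$z_decayed)
  expect_lt(max(abs(ne$ratio_to_U - 1)), 0.05)

  off <- two_patch_spec(a1 = 2, a2 = 3, d12 = 0.5, d21 = 0.5,
                        sigma1 = 1, sigma2 = 1, rho = 1)
  expect_error(synchronized_slice_check(off, c(1, 1)), "violate")
})

test_that("eigenweights are the stationary law of the dispersal chain", {
  expect_equal(dispersal_eigenweights(matrix(c(-1, 1, 1, -1), 2)),
               c(0.5, 0.5), tolerance = 1e-12)
  D <- matrix(c(-2, 2, 1, -1), 2, byrow = TRUE)
  expect_equal(dispersal_eigenweights(D), c(1, 2) / 3, tolerance = 1e-12)
  expect_error(dispersal_eigenweights(matrix(c(-1, 1, 0, 0), 2,
                                             byrow = TRUE)), "valid")
})

test_that("proportions collapse onto the eigenweights as dispersal grows", {
  m <- generate_fixture("two_patch_het", rho = 0)
  chk <- infinite_dispersal_check(m, delta_grid = c(1, 10, 100),
                                  T = 50, dt = 1e-3, seed = 6)
  expect_equal(chk$eigenweights, c(0.5, 0.5), tolerance = 1e-12)
  expect_true(chk$monotone_decreasing)
})

test_that("empirical histogram comparison behaves at its extremes", {
  d <- stationary_density_2p(het_spec(rho = 0))
  # constant sample vs a smooth density: essentially disjoint mass
  cmp <- empirical_density_compare(rep(0.5, 1000), d, bins = 50)
  expect_gt(cmp$value, 1.5)

  # point-mass branch reports the distance of the mean from the atom
  dpm <- stationary_density_2p(het_spec(rho = 1, sigma2 = sqrt(7)))
  expect_equal(dpm$branch, "point_mass")
  cmp2 <- empirical_density_compare(rep(0.3, 100), dpm)
  expect_equal(cmp2$type, "mean_distance")
  expect_equal(cmp2$value, abs(0.3 - dpm$ystar), tolerance = 1e-12)
})

test_that("long simplex runs match the stationary density", {
  sp <- het_spec(rho = 0)
  d <- stationary_density_2p(sp)
  st <- simulate_Ytilde(make_two_patch(sp), c(0.5, 0.5), T = 500,
                        dt = 1e-3, seed = 8)
  cmp <- empirical_density_compare(st, d, bins = 50, burn_frac = 0.1)
  expect_lt(cmp$value, 0.1)
})

test_that("closed-form verdicts match simulated tail behaviour", {
  # persistent fixture: positive r, boundary rarely visited
  mp <- generate_fixture("two_patch_het", rho = 0)
  expect_equal(classify_persistence(stochastic_growth_rate(mp))$verdict,
               "persistent")
  # extinct fixture: negative r and matching negative slopes
  spx <- two_patch_spec(a1 = 3, a2 = 3, d12 = 1, d21 = 1,
                        sigma1 = sqrt(7), sigma2 = sqrt(7), rho = 1)
  rx <- r_closedform_equal_sigma(spx)
  expect_equal(classify_persistence(rx)$verdict, "extinct")
  tr <- simulate_X(make_two_patch(spx), c(1, 1), T = 300, dt = 1e-3,
                   seed = 14)
  expect_true(all(extinction_slopes(tr)$slopes < 0))
})
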