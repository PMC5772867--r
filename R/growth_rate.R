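#' Stochastic growth rate of the linearized system
#'
#' The sign of
#' \deqn{r = \int_\Delta \left(a^\top y - \tfrac12 y^\top \Sigma y\right)
#'       \nu^*(dy)}
#' -- the Lyapunov exponent of the total population in the absence of
#' competition, with \eqn{\nu^*} the stationary law of the simplex
#' process -- separates persistence (positive `r`) from extinction (negative `r`).
#' `method = "auto"` dispatches on the model: one patch uses the closed
#' form `a - sigma^2/2`; two patches use quadrature against the explicit
#' stationary density of the proportion diffusion, or its closed form when
#' that diffusion is identically zero (equal volatilities under perfect
#' correlation); three or more patches fall back to Monte Carlo time
#' averaging.
#'
#' @param model a `patch_model` or a [two_patch_spec()].
#' @param method `"auto"`, `"single_patch"`, `"quadrature_2p"`,
#'   `"closedform_equal_sigma"`, or `"mc_timeaverage"`.
#' @param ... passed to the selected backend (e.g. `T`, `replicates`,
#'   `seed` for Monte Carlo).
#' @return a `growth_rate_result`: list with `r`, `se`, `method`, and a
#'   `diagnostics` list.
#' @export
stochastic_growth_rate <- function(model, method = "auto", ...) {
  if (inherits(model, "two_patch_spec")) model <- make_two_patch(model)
  stopifnot(inherits(model, "patch_model"))
  n <- model$n
  valid <- if (n == 1) "single_patch"
           else if (n == 2) c("quadrature_2p", "closedform_equal_sigma",
                              "mc_timeaverage")
           else "mc_timeaverage"
  if (method == "auto") {
    method <- if (n == 1) "single_patch"
      else if (n == 2) {
        sp <- as_two_patch_spec(model)
        if (ytilde_diffusion_scale(sp) < point_mass_tol(sp))
          "closedform_equal_sigma" else "quadrature_2p"
      } else "mc_timeaverage"
  } else if (!method %in% valid) {
    stop("method '", method, "' is not applicable for n = ", n,
         "; valid: ", paste(valid, collapse = ", "))
  }
  fn <- switch(method,
    single_patch = function(...) r_single_patch(model$a[1], model$Sigma[1, 1]),
    quadrature_2p = function(...) r_quadrature_2p(as_two_patch_spec(model), ...),
    closedform_equal_sigma =
      function(...) r_closedform_equal_sigma(as_two_patch_spec(model)),
    mc_timeaverage = function(...) r_mc_timeaverage(model, ...))
  args <- list(...)
  inner <- switch(method, single_patch = r_single_patch,
                  quadrature_2p = r_quadrature_2p,
                  closedform_equal_sigma = r_closedform_equal_sigma,
                  mc_timeaverage = r_mc_timeaverage)
  do.call(fn, args[intersect(names(args), names(formals(inner)))])
}

growth_rate_result <- function(r, se, method, diagnostics = list()) {
  structure(list(r = r, se = se, method = method, diagnostics = diagnostics),
            class = "growth_rate_result")
}

#' @export
print.growth_rate_result <- function(x, ...) {
  cat(sprintf("r = %.6g", x$r))
  if (x$se > 0) cat(sprintf(" (se %.3g)", x$se))
  cat("  [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Single-patch stochastic growth rate
#'
#' For one patch the growth rate is `a - sigma^2 / 2`: environmental
#' variance depresses the long-run growth of the geometric mean.
#'
#' @param a per-capita growth rate.
#' @param sigma_sq infinitesimal variance of the growth-rate noise.
#' @return a `growth_rate_result` with `se = 0`.
#' @export
r_single_patch <- function(a, sigma_sq) {
  stopifnot(sigma_sq >= 0)
  growth_rate_result(a - sigma_sq / 2, 0, "single_patch")
}

#' Monte Carlo time-average estimate of the growth rate
#'
#' Simulates the competition-free simplex process and averages the
#' integrand `a'y - y'Sigma y / 2` over `[burn_in, T]`, replicated with
#' independent noise streams; the standard error is the across-replicate
#' standard deviation of the means divided by `sqrt(replicates)`.
#'
#' @param model a `patch_model`.
#' @param T horizon; `burn_in` initial stretch discarded.
#' @param burn_in initial time discarded.
#' @param replicates number of independent replicates (>= 2).
#' @param dt step size.
#' @param seed root seed; per-replicate streams are derived from it.
#' @param y0 starting simplex point (default uniform).
#' @return a `growth_rate_result`.
#' @export
r_mc_timeaverage <- function(model, T = 1000, burn_in = 100, replicates = 16,
                             dt = 1e-3, seed = 1, y0 = NULL) {
  stopifnot(inherits(model, "patch_model"), T > burn_in, burn_in >= 0)
  if (replicates < 2) stop("'replicates' must be >= 2 to form a standard error")
  if (is.null(y0)) y0 <- rep(1 / model$n, model$n)
  seeds <- spawn_seeds(seed, replicates)
  means <- vapply(seeds, function(s) {
    attr(simulate_Ytilde(model, y0, T = T, dt = dt, seed = s,
                         burn_in = burn_in, thin = round(T / dt)), "favg")
  }, numeric(1))
  growth_rate_result(mean(means), stats::sd(means) / sqrt(replicates),
                     "mc_timeaverage",
                     diagnostics = list(T = T, burn_in = burn_in,
                                        replicates = replicates, dt = dt,
                                        replicate_means = means))
}

# squared-diffusion scale c = Sigma11 - 2 Sigma12 + Sigma22 of the
# two-patch proportion diffusion
ytilde_diffusion_scale <- function(spec) {
  Sg <- build_noise(sigma = c(spec$sigma1, spec$sigma2), rho = spec$rho)$Sigma
  Sg[1, 1] - 2 * Sg[1, 2] + Sg[2, 2]
}

point_mass_tol <- function(spec) {
  1e-12 * max(spec$sigma1^2, spec$sigma2^2)
}

#' Stationary density of the two-patch proportion diffusion
#'
#' Substituting `Y2 = 1 - Y1` into the simplex dynamics gives a scalar
#' diffusion for the patch-1 proportion `y` on (0, 1) with drift
#' \deqn{\mu(y) = d_{21} - (d_{12} + d_{21}) y + y(1-y)\left[(a_1 - a_2)
#'   - (\Sigma_{11} - \Sigma_{12}) y + (\Sigma_{22} - \Sigma_{12})(1 - y)
#'   \right]}
#' and squared diffusion
#' \eqn{s^2(y) = y^2 (1-y)^2 (\Sigma_{11} - 2\Sigma_{12} + \Sigma_{22})}.
#' When `s^2` is not identically zero, 0 and 1 are entrance boundaries and
#' the stationary density follows from the scale/speed construction,
#' \eqn{\rho \propto s^{-2} \exp \int 2\mu/s^2}; the integral is evaluated
#' in closed form by partial fractions, giving
#' \deqn{\rho_1^*(x) \propto x^{\beta - \alpha_1} (1-x)^{-\beta - \alpha_2}
#'   \exp\left(-\frac{2}{c}\left(\frac{d_{21}}{x} +
#'   \frac{d_{12}}{1-x}\right)\right)}
#' with `c` the diffusion scale, `beta = 2 (a1 - a2 + d21 - d12) / c` and
#' `alpha_i = 2 (Sigma_ii - Sigma_12) / c`. With independent noise this is
#' the classical two-patch density (`alpha_i = 2 sigma_i^2 /
#' (sigma_1^2 + sigma_2^2)`); under perfect correlation with unequal
#' volatilities the same shape holds with `c = (sigma_1 - sigma_2)^2` and
#' `alpha_1 = 2 sigma_1 / (sigma_1 - sigma_2)`,
#' `alpha_2 = -2 sigma_2 / (sigma_1 - sigma_2)`. When `s^2` vanishes
#' identically (equal volatilities, perfect correlation) the proportion
#' follows an ODE and the stationary law is a point mass at its
#' equilibrium `y*`.
#'
#' Normalization and the first two moments are computed by adaptive
#' quadrature in log scale (the boundary factors vanish faster than any
#' power, so integration over (0, 1) is direct).
#'
#' @param spec a [two_patch_spec()] with `d12 > 0` and `d21 > 0` (the
#'   boundary factors require migration into both patches).
#' @param rel_tol quadrature tolerance.
#' @return object of class `stationary_density_2p`: branch
#'   (`"nondegenerate"`, `"degenerate_unequal"` or `"point_mass"`),
#'   exponents (`alpha1`, `alpha2`, `beta_exp`), diffusion `scale`, log
#'   normalization `logC`, moments `m1`, `m2`, `ystar` (point-mass branch),
#'   and the normalized density function `pdf`.
#' @export
stationary_density_2p <- function(spec, rel_tol = 1e-10) {
  stopifnot(inherits(spec, "two_patch_spec"))
  nz <- build_noise(sigma = c(spec$sigma1, spec$sigma2), rho = spec$rho)
  Sg <- nz$Sigma
  cc <- Sg[1, 1] - 2 * Sg[1, 2] + Sg[2, 2]

  if (cc < point_mass_tol(spec)) {
    ys <- equilibrium_proportion(spec)
    return(structure(list(branch = "point_mass", exponents = NULL,
                          scale = 0, logC = NA_real_, m1 = ys, m2 = ys^2,
                          ystar = ys, pdf = NULL, cdf = NULL, spec = spec),
                     class = "stationary_density_2p"))
  }
  if (spec$d12 <= 0 || spec$d21 <= 0)
    stop("stationary density requires d12 > 0 and d21 > 0 ",
         "(dispersal into both patches); the model is reducible otherwise")

  beta_exp <- 2 * (spec$a1 - spec$a2 + spec$d21 - spec$d12) / cc
  alpha1 <- 2 * (Sg[1, 1] - Sg[1, 2]) / cc
  alpha2 <- 2 * (Sg[2, 2] - Sg[1, 2]) / cc
  d12 <- spec$d12; d21 <- spec$d21
  logf <- function(x) {
    (beta_exp - alpha1) * log(x) + (-beta_exp - alpha2) * log1p(-x) -
      (2 / cc) * (d21 / x + d12 / (1 - x))
  }
  # normalize in log space around the grid maximum
  xg <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  M <- max(logf(xg))
  Z <- stats::integrate(function(x) exp(logf(x) - M), 0, 1,
                        rel.tol = rel_tol, abs.tol = 0,
                        subdivisions = 500L)$value
  logC <- -(M + log(Z))
  pdf <- function(x) {
    out <- numeric(length(x))
    inb <- x > 0 & x < 1
    out[inb] <- exp(logf(x[inb]) + logC)
    out
  }
  m1 <- stats::integrate(function(x) x * pdf(x), 0, 1, rel.tol = rel_tol,
                         abs.tol = 0, subdivisions = 500L)$value
  m2 <- stats::integrate(function(x) x^2 * pdf(x), 0, 1, rel.tol = rel_tol,
                         abs.tol = 0, subdivisions = 500L)$value
  branch <- if (nz$degenerate) "degenerate_unequal" else "nondegenerate"
  structure(list(branch = branch,
                 exponents = c(alpha1 = alpha1, alpha2 = alpha2,
                               beta_exp = beta_exp),
                 scale = cc, logC = logC, m1 = m1, m2 = m2,
                 ystar = NA_real_, pdf = pdf, spec = spec),
            class = "stationary_density_2p")
}

#' @export
print.stationary_density_2p <- function(x, ...) {
  cat("Two-patch stationary proportion density, branch:", x$branch, "\n")
  if (x$branch == "point_mass") {
    cat(sprintf("  point mass at y* = %.6g\n", x$ystar))
  } else {
    cat(sprintf("  exponents: x^%.4g (1-x)^%.4g, diffusion scale %.4g\n",
                x$exponents["beta_exp"] - x$exponents["alpha1"],
                -x$exponents["beta_exp"] - x$exponents["alpha2"], x$scale))
    cat(sprintf("  moments: m1 = %.6g, m2 = %.6g\n", x$m1, x$m2))
  }
  invisible(x)
}

# equilibrium of the deterministic proportion ODE:
# (a1 - a2)(1 - y) y + d21 - (d12 + d21) y = 0, unique root in [0, 1]
equilibrium_proportion <- function(spec) {
  da <- spec$a1 - spec$a2
  if (abs(da) < 1e-14) {
    if (spec$d12 + spec$d21 <= 0) return(0.5)
    return(spec$d21 / (spec$d12 + spec$d21))
  }
  if (abs(spec$d12 - spec$d21) < 1e-14) {
    al <- spec$d12  # symmetric dispersal: closed-form root
    return((da - 2 * al + sqrt(da^2 + 4 * al^2)) / (2 * da))
  }
  f <- function(y) da * (1 - y) * y + spec$d21 - (spec$d12 + spec$d21) * y
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Growth rate by quadrature against the stationary proportion density
#'
#' Evaluates the defining integral of the growth rate under the explicit
#' two-patch stationary density: with `m1`, `m2` the first two moments of
#' the patch-1 proportion,
#' \deqn{r = a_2 - \Sigma_{22}/2 + (a_1 - a_2 + \Sigma_{22} - \Sigma_{12})
#'       m_1 - \tfrac{c}{2} m_2,}
#' `c` being the diffusion scale `Sigma11 - 2 Sigma12 + Sigma22`. With
#' independent noise this reduces to the classical formula with
#' coefficient `a1 - a2 + sigma2^2` and scale `sigma1^2 + sigma2^2`.
#'
#' @param spec a [two_patch_spec()].
#' @param rel_tol quadrature tolerance.
#' @return a `growth_rate_result` with `se = 0`.
#' @export
r_quadrature_2p <- function(spec, rel_tol = 1e-10) {
  dens <- stationary_density_2p(spec, rel_tol = rel_tol)
  if (dens$branch == "point_mass")
    stop("proportion diffusion is identically zero; ",
         "use r_closedform_equal_sigma()")
  Sg <- build_noise(sigma = c(spec$sigma1, spec$sigma2), rho = spec$rho)$Sigma
  r <- spec$a2 - Sg[2, 2] / 2 +
    (spec$a1 - spec$a2 + Sg[2, 2] - Sg[1, 2]) * dens$m1 -
    dens$scale / 2 * dens$m2
  growth_rate_result(r, 0, "quadrature_2p",
                     diagnostics = list(branch = dens$branch, m1 = dens$m1,
                                        m2 = dens$m2, rel_tol = rel_tol))
}

#' Closed-form growth rate under equal volatilities and perfect correlation
#'
#' When both patches share one Brownian motion with equal volatility, the
#' proportion diffusion is noiseless and converges to the equilibrium `y*`
#' of `(a1 - a2)(1 - y) y + d21 - (d12 + d21) y = 0`; the stationary law is
#' the point mass there and
#' \deqn{r = a_2 - \sigma^2/2 + (a_1 - a_2) y^\star}
#' (on the simplex `y' Sigma y = sigma^2` identically, so the variance
#' penalty does not depend on `y*`). For symmetric dispersal
#' `d12 = d21 = alpha` this equals
#' `(a1 + a2 - 2 alpha + sqrt((a1 - a2)^2 + 4 alpha^2)) / 2 - sigma^2/2`,
#' a strictly decreasing function of `alpha`.
#'
#' @param spec a [two_patch_spec()] with `sigma1 = sigma2` and `rho = 1`.
#' @return a `growth_rate_result` with `se = 0` and the equilibrium `y*`
#'   in the diagnostics.
#' @export
r_closedform_equal_sigma <- function(spec) {
  stopifnot(inherits(spec, "two_patch_spec"))
  if (ytilde_diffusion_scale(spec) >= point_mass_tol(spec))
    stop("proportion diffusion is not identically zero ",
         "(needs sigma1 = sigma2 and rho = 1); use r_quadrature_2p()")
  ys <- equilibrium_proportion(spec)
  r <- spec$a2 - spec$sigma2^2 / 2 + (spec$a1 - spec$a2) * ys
  growth_rate_result(r, 0, "closedform_equal_sigma",
                     diagnostics = list(ystar = ys))
}

#' Large-dispersal approximation of the growth rate
#'
#' For symmetric dispersal `alpha` under equal volatilities and perfect
#' correlation, expanding the closed form for large `alpha` gives
#' \deqn{r \approx \frac{a_1 + a_2}{2} - \frac{\sigma^2}{2}
#'       + \frac{(a_1 - a_2)^2}{8 \alpha},}
#' approaching the spatial-average rate `(a1 + a2)/2 - sigma^2/2` as
#' `alpha` grows. Intended for cross-checking the exact closed form.
#'
#' @param spec a [two_patch_spec()] with `d12 = d21 > 0`.
#' @return a `growth_rate_result`.
#' @export
r_large_dispersal_approx <- function(spec) {
  stopifnot(inherits(spec, "two_patch_spec"))
  if (abs(spec$d12 - spec$d21) > 1e-12 || spec$d12 <= 0)
    stop("approximation requires symmetric dispersal d12 = d21 > 0")
  alpha <- spec$d12
  sigma_sq <- spec$sigma1 * spec$sigma2  # equal-sigma slice: sigma^2
  r <- (spec$a1 + spec$a2) / 2 - sigma_sq / 2 +
    (spec$a1 - spec$a2)^2 / (8 * alpha)
  growth_rate_result(r, 0, "large_dispersal_approx",
                     diagnostics = list(alpha = alpha))
}

#' Draw samples from a two-patch stationary density
#'
#' Inverse-CDF sampling on a fine grid; used for calibrating empirical
#' histogram comparisons.
#'
#' @param dens a non-point-mass `stationary_density_2p`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of draws in (0, 1).
#' @export
sample_stationary_2p <- function(dens, n, seed = 1) {
  stopifnot(inherits(dens, "stationary_density_2p"))
  if (dens$branch == "point_mass") return(rep(dens$ystar, n))
  xg <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  px <- dens$pdf(xg)
  cdf <- cumsum((px[-1] + px[-length(px)]) / 2 * diff(xg))
  cdf <- c(0, cdf / cdf[length(cdf)])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  u <- stats::runif(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stats::approx(cdf, xg, xout = u, ties = "ordered")$y
}
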