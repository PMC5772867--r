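#' Classify persistence from a growth-rate estimate
#'
#' Positive `r` implies convergence of abundances to a unique invariant
#' law on the open orthant; negative `r` implies almost-sure exponential
#' extinction of every patch at rate `r`. The boundary case (`r` exactly 0) is outside
#' the theory, so estimates within `tolerance` (or within three standard
#' errors for Monte Carlo estimates) are reported as inconclusive.
#'
#' @param r_result a `growth_rate_result`.
#' @param tolerance half-width of the indeterminate band around 0.
#' @return a `classification_result` with `verdict` (`"persistent"`,
#'   `"extinct"` or `"inconclusive"`), `r_used`, and the band used.
#' @export
classify_persistence <- function(r_result, tolerance = 1e-3) {
  stopifnot(inherits(r_result, "growth_rate_result"), tolerance >= 0)
  band <- max(tolerance, 3 * r_result$se)
  verdict <- if (r_result$r > band) "persistent"
    else if (r_result$r < -band) "extinct"
    else "inconclusive"
  structure(list(verdict = verdict, r_used = r_result, tolerance = band),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s (r = %.4g, band +/- %.3g)\n", toupper(x$verdict),
              x$r_used$r, x$tolerance))
  invisible(x)
}

#' Fraction of time spent near the extinction boundary
#'
#' The normalized occupation measure of the set where some patch abundance
#' is at most `eta`: the fraction of stored grid times (left-endpoint rule)
#' with `min_i X_i(t) <= eta`. Stochastic persistence keeps this fraction
#' small for small `eta`.
#'
#' @param traj a `patch_trajectory`.
#' @param eta positive threshold.
#' @return an `occupation_stats` list: `eta`, `fraction`, `t_window`.
#' @export
occupation_fraction <- function(traj, eta) {
  stopifnot(inherits(traj, "patch_trajectory"), eta > 0)
  if (nrow(traj$X) < 2) stop("trajectory has no time steps")
  mins <- apply(traj$X[-nrow(traj$X), , drop = FALSE], 1, min)
  structure(list(eta = eta, fraction = mean(mins <= eta),
                 t_window = range(traj$times)),
            class = "occupation_stats")
}

#' Per-patch extinction-rate slopes
#'
#' In the extinction regime every patch's log-abundance decays at the same
#' almost-sure rate `r`. Fits least-squares slopes of `ln X_i(t)` against
#' `t` on the tail window (final `window_frac` of the horizon, default the
#' final half, to avoid transient bias) and reports their spread.
#'
#' @param traj a `patch_trajectory` with strictly positive abundances on
#'   the window.
#' @param window_frac fraction of the horizon used, from the end.
#' @return list with `slopes` (one per patch), `spread` (max - min), and
#'   the fitted window.
#' @export
extinction_slopes <- function(traj, window_frac = 0.5) {
  stopifnot(inherits(traj, "patch_trajectory"), window_frac > 0,
            window_frac <= 1)
  t <- traj$times
  keep <- t >= max(t) * (1 - window_frac)
  Xw <- traj$X[keep, , drop = FALSE]
  if (any(Xw <= 0))
    stop("zero abundance in the fitted window; shorten the window")
  tw <- t[keep]
  slopes <- apply(Xw, 2, function(x) unname(stats::lm.fit(
    cbind(1, tw), log(x))$coefficients[2]))
  list(slopes = slopes, spread = max(slopes) - min(slopes),
       window = range(tw))
}

#' Construct a bounded perturbation of a patch model
#'
#' Builds a model whose growth rates, dispersal matrix and noise loading
#' deviate from the base by at most `theta` in sup (max absolute entry)
#' norm, for probing robustness of persistence: small enough perturbations
#' cannot flip a persistent system to extinction. Constant mode adds
#' seeded uniform offsets of magnitude at most `0.99 * theta` to `a`, the
#' off-diagonal entries of `D` (diagonal re-balanced to preserve zero row
#' sums) and `Gamma`; for a fixed seed the offsets scale linearly in
#' `theta`, so deviations shrink with it. State-dependent mode multiplies
#' the same offsets by the bounded smooth bump `1/(1 + |x|^2)`, yielding
#' density-dependent coefficient functions with the same sup bound.
#'
#' @param base a `patch_model`.
#' @param theta perturbation bound (>= 0). Must not exceed the smallest
#'   positive off-diagonal dispersal rate, else `D` could lose its sign
#'   constraints.
#' @param mode `"constant"` or `"state_dependent"`.
#' @param seed integer seed for the offsets.
#' @return a `perturbed_model`: list with `model` (a valid `patch_model`
#'   in constant mode), `theta`, `mode`, measured `deviations`, and in
#'   state-dependent mode the coefficient functions `a_fun`, `D_fun`,
#'   `Gamma_fun`.
#' @export
make_theta_perturbation <- function(base, theta,
                                    mode = c("constant", "state_dependent"),
                                    seed = 1) {
  stopifnot(inherits(base, "patch_model"), theta >= 0)
  mode <- match.arg(mode)
  n <- base$n
  offdiag <- base$D[row(base$D) != col(base$D)]
  minpos <- if (any(offdiag > 0)) min(offdiag[offdiag > 0]) else Inf
  if (0.99 * theta > minpos)
    stop("theta = ", theta, " exceeds the smallest positive dispersal rate (",
         signif(minpos, 3), "); choose a smaller theta")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  u_a <- stats::runif(n, -1, 1)
  u_D <- matrix(stats::runif(n * n, -1, 1), n, n)
  u_G <- matrix(stats::runif(length(base$Gamma), -1, 1), nrow(base$Gamma))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  # zero off-diagonal rates are only perturbed inward (stay >= 0)
  zero_off <- base$D == 0 & row(u_D) != col(u_D)
  u_D[zero_off] <- abs(u_D[zero_off])
  diag(u_D) <- 0

  scale <- 0.99 * theta
  a_hat <- base$a + scale * u_a
  D_pert <- scale * u_D
  diag(D_pert) <- -rowSums(D_pert)
  # re-scale so the dispersal deviation (incl. re-balanced diagonal) <= scale
  mx <- max(abs(D_pert))
  if (mx > scale && mx > 0) D_pert <- D_pert * (scale / mx)
  D_hat <- base$D + D_pert
  G_hat <- base$Gamma + scale * u_G

  deviations <- c(a = max(abs(a_hat - base$a)),
                  D = max(abs(D_hat - base$D)),
                  Gamma = max(abs(G_hat - base$Gamma)))

  if (mode == "constant") {
    model <- patch_model(a = a_hat,
                         competition = if (!is.null(base$kappa)) base$kappa
                                       else base$b,
                         D = D_hat, Gamma = G_hat)
    return(structure(list(base = base, model = model, theta = theta,
                          mode = mode, deviations = deviations),
                     class = "perturbed_model"))
  }
  bump <- function(x) 1 / (1 + sum(x^2))
  structure(list(base = base, model = NULL, theta = theta, mode = mode,
                 deviations = deviations,
                 a_fun = function(x) base$a + scale * u_a * bump(x),
                 D_fun = function(x) {
                   P <- scale * u_D * bump(x)
                   diag(P) <- -rowSums(P)
                   mxx <- max(abs(P))
                   if (mxx > scale && mxx > 0) P <- P * (scale / mxx)
                   base$D + P
                 },
                 Gamma_fun = function(x) base$Gamma + scale * u_G * bump(x)),
            class = "perturbed_model")
}

#' Synchronization diagnostics on the degenerate manifold slice
#'
#' On the parameter slice with equal volatilities, equal linear
#' competition and `2 (d21 - d12) = a2 - a1` under one shared Brownian
#' motion, the two abundances synchronize: equal starts stay equal
#' forever, the ratio `Z = X1 / X2` approaches 1 monotonically from
#' unequal starts, and both abundances track the scalar logistic diffusion
#' `dU = U (a1 - d12 + d21 - b U) dt + sigma U dB` on the same Brownian
#' path, so the invariant law concentrates on the diagonal
#' `{x1 = x2}`. The growth rate on this slice is
#' `r` equal to `a1 - d12 + d21 - sigma^2 / 2`.
#'
#' @param spec a [two_patch_spec()] on the slice (checked).
#' @param x0 initial abundances (length 2, positive).
#' @param T horizon; `dt` step; `seed` seed.
#' @param dt time step.
#' @param seed integer seed.
#' @return list with `r`, `max_abs_diff` (`|X1 - X2|` along the path),
#'   `z_sign_constant`, `z_decayed` (ratio checks), `ratio_to_U`
#'   (terminal `X_i(T)/U(T)`), and the co-simulated paths.
#' @export
synchronized_slice_check <- function(spec, x0, T = 200, dt = 1e-3, seed = 1) {
  stopifnot(inherits(spec, "two_patch_spec"), length(x0) == 2, all(x0 > 0))
  if (abs(spec$sigma1 - spec$sigma2) > 1e-12 || abs(spec$rho - 1) > 1e-12)
    stop("slice requires sigma1 = sigma2 and rho = 1")
  if (abs(spec$comp1 - spec$comp2) > 1e-12)
    stop("slice requires equal competition coefficients")
  slice_gap <- 2 * (spec$d21 - spec$d12) - (spec$a2 - spec$a1)
  if (abs(slice_gap) > 1e-10)
    stop("parameters violate 2(d21 - d12) = a2 - a1 (gap ", signif(slice_gap, 3), ")")
  # ratio-equation identity that makes Z autonomous on the slice
  ident <- spec$d21 + (spec$a1 - spec$a2 - spec$d12 + spec$d21) - spec$d12
  stopifnot(abs(ident) < 1e-10)

  model <- make_two_patch(spec)
  noise <- brownian_increments(T, dt, 1, seed)  # one shared Brownian motion
  traj <- simulate_X(model, x0, T = T, dt = dt, scheme = "em_clamped",
                     noise = noise, seed = seed)
  sig <- spec$sigma1
  rr <- spec$a1 - spec$d12 + spec$d21 - sig^2 / 2
  # reference logistic diffusion on the same path (same EM discretization)
  K <- nrow(noise$increments)
  thin <- pick_thin(K)
  Ukeep <- numeric(K / thin + 1)
  u <- x0[2]; Ukeep[1] <- u; row <- 2L
  aU <- spec$a1 - spec$d12 + spec$d21; bU <- spec$comp1
  dB <- noise$increments[, 1]
  for (step in seq_len(K)) {
    u <- max(u + u * (aU - bU * u) * dt + sig * u * dB[step], 0)
    if (step %% thin == 0L) { Ukeep[row] <- u; row <- row + 1L }
  }
  Z <- traj$X[, 1] / traj$X[, 2]
  z0 <- x0[1] / x0[2]
  # Z - 1 keeps the sign of Z(0) - 1 until it underflows to 0 at machine level
  list(r = rr,
       max_abs_diff = max(abs(traj$X[, 1] - traj$X[, 2])),
       z_sign_constant = all((Z - 1) * sign(z0 - 1) >= -1e-12) || z0 == 1,
       z_decayed = abs(Z[length(Z)] - 1) < abs(z0 - 1) || z0 == 1,
       ratio_to_U = traj$X[nrow(traj$X), ] / Ukeep[length(Ukeep)],
       trajectory = traj, U = Ukeep)
}

#' Dominant left eigenvector of a dispersal matrix
#'
#' The normalized left null vector of the generator `D` (entrywise
#' positive when `D` is irreducible); the stationary patch distribution of
#' the dispersal Markov chain, toward which proportions collapse in the
#' infinite-dispersal limit.
#'
#' @param D dispersal matrix.
#' @return numeric vector summing to 1.
#' @export
dispersal_eigenweights <- function(D) {
  rep <- validate_dispersal(D)
  if (!rep$passed) stop("eigenweights need a valid dispersal matrix: ", rep$detail)
  e <- eigen(t(D))
  i <- which.min(abs(e$values))
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  if (any(w <= 0)) stop("left null vector is not entrywise positive")
  w
}

#' Infinite-dispersal limit check
#'
#' Scaling the dispersal matrix by `delta` and letting `delta` grow, the
#' patch proportions collapse onto the dominant left eigenvector of `D`;
#' the whole system then behaves like a single well-mixed population.
#' Simulates the full model at each `delta` (sharing the noise path) and
#' reports the tail-averaged worst-patch deviation
#' `max_i |Y_i(t) - w_i|`, which should decrease along increasing `delta`.
#'
#' @param model a `patch_model` with linear competition.
#' @param delta_grid increasing dispersal multipliers.
#' @param x0 initial abundances; `T`, `dt`, `seed` as elsewhere.
#' @param T horizon.
#' @param dt time step.
#' @param seed integer seed.
#' @param burn_frac fraction of the horizon discarded before averaging.
#' @return list with `eigenweights`, `delta_grid`, `deviation` (one per
#'   `delta`), and `monotone_decreasing`.
#' @export
infinite_dispersal_check <- function(model, delta_grid = c(1, 10, 100),
                                     x0 = NULL, T = 100, dt = 1e-3, seed = 1,
                                     burn_frac = 0.2) {
  stopifnot(inherits(model, "patch_model"), all(diff(delta_grid) > 0))
  w <- dispersal_eigenweights(model$D)
  if (is.null(x0)) x0 <- rep(1, model$n)
  noise <- brownian_increments(T, dt, nrow(model$Gamma), seed)
  dev <- vapply(delta_grid, function(d) {
    m <- patch_model(model$a,
                     if (!is.null(model$kappa)) model$kappa else model$b,
                     model$D * d, Gamma = model$Gamma)
    tr <- simulate_X(m, x0, T = T, dt = dt, noise = noise, seed = seed)
    keep <- tr$times >= burn_frac * T
    mean(apply(abs(tr$Y[keep, , drop = FALSE] -
                     matrix(w, sum(keep), model$n, byrow = TRUE)), 1, max))
  }, numeric(1))
  list(eigenweights = w, delta_grid = delta_grid, deviation = dev,
       monotone_decreasing = all(diff(dev) < 0))
}

#' Compare an empirical proportion histogram with a stationary density
#'
#' Bins the patch-1 proportion of a simplex trajectory (burn-in removed)
#' and returns the L1 distance `sum_b |phat_b - p_b|` to the density's bin
#' masses (0 is perfect agreement, 2 is disjoint support). For a
#' point-mass density the distance of the empirical mean from the atom
#' `y*` is returned instead.
#'
#' @param simplex_traj a `simplex_trajectory`, or a numeric vector of
#'   proportion samples.
#' @param density a `stationary_density_2p`.
#' @param bins number of equal-width bins on (0, 1).
#' @param burn_frac fraction of stored points discarded from the front
#'   (ignored for a numeric vector).
#' @return list with `type` (`"L1"` or `"mean_distance"`) and `value`.
#' @export
empirical_density_compare <- function(simplex_traj, density, bins = 50,
                                      burn_frac = 0.1) {
  stopifnot(inherits(density, "stationary_density_2p"))
  y <- if (inherits(simplex_traj, "simplex_trajectory")) {
    v <- simplex_traj$Y[, 1]
    nb <- floor(length(v) * burn_frac)
    if (nb > 0) v[-seq_len(nb)] else v
  } else as.numeric(simplex_traj)
  if (!length(y)) stop("empty trajectory")
  if (density$branch == "point_mass")
    return(list(type = "mean_distance", value = abs(mean(y) - density$ystar)))
  br <- seq(0, 1, length.out = bins + 1)
  phat <- tabulate(findInterval(y, br, rightmost.closed = TRUE,
                                all.inside = TRUE), bins) / length(y)
  xg <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  px <- density$pdf(xg)
  cdfg <- c(0, cumsum((px[-1] + px[-length(px)]) / 2 * diff(xg)))
  cdfg <- cdfg / cdfg[length(cdfg)]
  p <- diff(stats::approx(xg, cdfg, xout = br, rule = 2, ties = "ordered")$y)
  list(type = "L1", value = sum(abs(phat - p)))
}
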