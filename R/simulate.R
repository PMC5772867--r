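#' Seeded Brownian increments
#'
#' Generates the `K x k` matrix of increments `dB` used by the integrators,
#' with `K = round(T / dt)` steps and standard deviation `sqrt(dt)` per
#' increment. Sharing one noise path across schemes or models gives
#' same-path coupling for comparisons.
#'
#' @param T time horizon.
#' @param dt step size.
#' @param k number of independent Brownian motions.
#' @param seed integer seed.
#' @return object of class `noise_path`: list with `times`, `increments`
#'   (`K x k`), `dt`, `seed`.
#' @export
brownian_increments <- function(T, dt, k, seed) {
  K <- round(T / dt)
  stopifnot(K >= 1, dt > 0, k >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  inc <- matrix(stats::rnorm(K * k, sd = sqrt(dt)), nrow = K, ncol = k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(times = seq(0, K * dt, by = dt), increments = inc,
                 dt = dt, seed = seed),
            class = "noise_path")
}

# Derive independent per-replicate seeds from a root seed.
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

# choose a thinning stride dividing K, targeting ~max_keep stored points
pick_thin <- function(K, max_keep = 20000L) {
  thin <- max(1L, as.integer(ceiling(K / max_keep)))
  while (K %% thin != 0L) thin <- thin + 1L
  thin
}

new_trajectory <- function(times, X, seed, scheme, dt) {
  S <- rowSums(X)
  Y <- X / ifelse(S > 0, S, 1)
  structure(list(times = times, X = X, S = S, Y = Y,
                 seed = seed, scheme = scheme, dt = dt),
            class = "patch_trajectory")
}

#' @export
print.patch_trajectory <- function(x, ...) {
  cat(sprintf("Patch trajectory: %d patches, %d stored points on [0, %g], scheme %s\n",
              ncol(x$X), length(x$times), max(x$times), x$scheme))
  invisible(x)
}

#' Simulate the abundance SDE
#'
#' Integrates the density-dependent patch system
#' \deqn{dX_i = (X_i(a_i - b_i(X_i)) + \sum_j D_{ji} X_j)\,dt + X_i\,dE_i}
#' by Euler-Maruyama. The default `ys_transform` scheme integrates the
#' proportion/log-total decomposition `(Y, ln S)` and maps back
#' `X_i = Y_i S`, so abundances stay positive and totals cannot overflow;
#' `em_clamped` steps the abundances directly, clamping negative proposals
#' to 0, and is retained as a cross-check. Both schemes consume the same
#' Brownian increments for a given seed.
#'
#' @param model a `patch_model`.
#' @param x0 initial abundances (nonnegative; all-zero is absorbing).
#' @param T horizon, `dt` step, `seed` integer seed.
#' @param dt time step.
#' @param seed integer seed (ignored when `noise` is given).
#' @param scheme `"ys_transform"` (default) or `"em_clamped"`.
#' @param noise optional [brownian_increments()] object to reuse a path.
#' @param thin store every `thin`-th step (`NULL` picks automatically).
#' @return a `patch_trajectory` with `times`, `X`, totals `S`, proportions
#'   `Y`, and the seed/scheme metadata.
#' @export
simulate_X <- function(model, x0, T, dt = 1e-3, seed = 1,
                       scheme = c("ys_transform", "em_clamped"),
                       noise = NULL, thin = NULL) {
  stopifnot(inherits(model, "patch_model"), T >= dt, dt > 0)
  scheme <- match.arg(scheme)
  x0 <- as.numeric(x0)
  if (length(x0) != model$n) stop("'x0' must have one entry per patch")
  if (any(x0 < 0)) stop("'x0' must be nonnegative")
  K <- round(T / dt)
  if (is.null(noise)) noise <- brownian_increments(T, dt, nrow(model$Gamma), seed)
  if (is.null(thin)) thin <- pick_thin(K)
  times <- seq(0, K * dt, by = thin * dt)

  if (sum(x0) == 0) {
    X <- matrix(0, length(times), model$n)
    return(new_trajectory(times, X, seed, scheme, dt))
  }
  linear <- !is.null(model$kappa)
  if (!linear) {
    X <- r_integrate_x(model, x0, dt, noise$increments, thin, scheme)
    return(new_trajectory(times, X, seed, scheme, dt))
  }
  if (scheme == "em_clamped") {
    X <- cpp_sim_x_em(model$a, model$kappa, TRUE, model$D, model$Gamma,
                      x0, dt, noise$increments, thin)
  } else {
    s0 <- sum(x0)
    out <- cpp_sim_ys(model$a, model$D, model$Gamma, model$Sigma,
                      model$kappa, TRUE, x0 / s0, log(s0), dt,
                      noise$increments, thin, 0L)
    X <- out$Y * exp(out$lnS)
  }
  new_trajectory(times, X, seed, scheme, dt)
}

# R fallback integrator for models with non-linear competition functions
r_integrate_x <- function(model, x0, dt, dB, thin, scheme) {
  n <- model$n; K <- nrow(dB)
  keep <- matrix(NA_real_, K / thin + 1, n)
  x <- x0; keep[1, ] <- x; row <- 2L
  bfun <- model$b
  for (step in seq_len(K)) {
    dE <- as.numeric(crossprod(model$Gamma, dB[step, ]))
    bx <- vapply(seq_len(n), function(i) bfun[[i]](x[i]), numeric(1))
    drift <- x * (model$a - bx) + as.numeric(crossprod(model$D, x))
    x <- pmax(x + drift * dt + x * dE, 0)
    if (step %% thin == 0L) { keep[row, ] <- x; row <- row + 1L }
  }
  keep
}

#' Simulate the proportion/total decomposition
#'
#' Integrates the `(Y, ln S)` system directly: proportions `Y` live on the
#' simplex (each Euler step is projected back by truncating negatives and
#' renormalizing) and the total `S` is advanced in log scale with the Ito
#' correction, so it is positive by construction.
#'
#' @param model a `patch_model` (linear competition required for the
#'   compiled path).
#' @param y0 initial point on the simplex.
#' @param s0 initial total (> 0).
#' @inheritParams simulate_X
#' @return list with `Y` (a `simplex_trajectory`) and `S` (numeric vector
#'   of totals at the stored times).
#' @export
simulate_YS <- function(model, y0, s0, T, dt = 1e-3, seed = 1,
                        noise = NULL, thin = NULL) {
  stopifnot(inherits(model, "patch_model"), s0 > 0, T >= dt)
  y0 <- as.numeric(y0)
  if (length(y0) != model$n || any(y0 < 0) || abs(sum(y0) - 1) > 1e-9)
    stop("'y0' must be on the simplex (nonnegative, sum 1)")
  if (is.null(model$kappa)) stop("compiled (Y, ln S) path requires linear competition")
  K <- round(T / dt)
  if (is.null(noise)) noise <- brownian_increments(T, dt, nrow(model$Gamma), seed)
  if (is.null(thin)) thin <- pick_thin(K)
  out <- cpp_sim_ys(model$a, model$D, model$Gamma, model$Sigma, model$kappa,
                    TRUE, y0, log(s0), dt, noise$increments, thin, 0L)
  times <- seq(0, K * dt, by = thin * dt)
  list(Y = structure(list(times = times, Y = out$Y, seed = seed, dt = dt),
                     class = "simplex_trajectory"),
       S = exp(out$lnS))
}

#' Simulate the competition-free simplex process
#'
#' The proportions of the linearized (competition-free) system form an
#' autonomous diffusion on the simplex; its stationary law defines the
#' stochastic growth rate. Under equal volatilities and perfect correlation
#' the noise term vanishes identically and the dynamics reduce to an ODE.
#'
#' @param model a `patch_model` (competition is ignored).
#' @param y0 initial simplex point.
#' @inheritParams simulate_X
#' @param burn_in time discarded before accumulating the integrand average.
#' @return a `simplex_trajectory`; attribute `"favg"` holds the time
#'   average of `a'y - y'Sigma y / 2` over `[burn_in, T]`.
#' @export
simulate_Ytilde <- function(model, y0, T, dt = 1e-3, seed = 1,
                            noise = NULL, thin = NULL, burn_in = 0) {
  stopifnot(inherits(model, "patch_model"), T >= dt, burn_in >= 0, burn_in < T)
  y0 <- as.numeric(y0)
  if (length(y0) != model$n || any(y0 < 0) || abs(sum(y0) - 1) > 1e-9)
    stop("'y0' must be on the simplex (nonnegative, sum 1)")
  K <- round(T / dt)
  if (is.null(noise)) noise <- brownian_increments(T, dt, nrow(model$Gamma), seed)
  if (is.null(thin)) thin <- pick_thin(K)
  kap <- if (is.null(model$kappa)) rep(0, model$n) else model$kappa
  out <- cpp_sim_ys(model$a, model$D, model$Gamma, model$Sigma, kap,
                    FALSE, y0, 0, dt, noise$increments, thin,
                    as.integer(round(burn_in / dt)))
  times <- seq(0, K * dt, by = thin * dt)
  structure(list(times = times, Y = out$Y, seed = seed, dt = dt),
            class = "simplex_trajectory", favg = out$favg, lnS = out$lnS)
}

#' @export
print.simplex_trajectory <- function(x, ...) {
  cat(sprintf("Simplex trajectory: %d patches, %d stored points on [0, %g]\n",
              ncol(x$Y), length(x$times), max(x$times)))
  invisible(x)
}

#' Simulate the linearized (competition-free) abundance system
#'
#' Drops the competition terms from the abundance SDE. The log-total
#' `ln S(t)` is accumulated alongside the proportions to avoid overflow on
#' long horizons; `ln S(T) / T` estimates the stochastic growth rate.
#'
#' @param model a `patch_model` (competition ignored).
#' @param x0 initial abundances, not all zero.
#' @inheritParams simulate_X
#' @return list with `X` (a `patch_trajectory`, abundances
#'   `Y * exp(ln S)`), `lnS` (log-totals at stored times), and `Y` (the
#'   proportion matrix).
#' @export
simulate_linearized <- function(model, x0, T, dt = 1e-3, seed = 1,
                                noise = NULL, thin = NULL) {
  stopifnot(inherits(model, "patch_model"), T >= dt)
  x0 <- as.numeric(x0)
  if (any(x0 < 0) || sum(x0) <= 0) stop("'x0' must be nonnegative, not all zero")
  K <- round(T / dt)
  if (is.null(noise)) noise <- brownian_increments(T, dt, nrow(model$Gamma), seed)
  if (is.null(thin)) thin <- pick_thin(K)
  s0 <- sum(x0)
  out <- cpp_sim_ys(model$a, model$D, model$Gamma, model$Sigma,
                    rep(0, model$n), FALSE, x0 / s0, log(s0), dt,
                    noise$increments, thin, 0L)
  times <- seq(0, K * dt, by = thin * dt)
  X <- out$Y * exp(pmin(out$lnS, 700))
  list(X = new_trajectory(times, X, seed, "ys_transform", dt),
       lnS = out$lnS, Y = out$Y)
}
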