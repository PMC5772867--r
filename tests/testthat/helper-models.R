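# shared fixtures and small oracles for the test suite

het_spec <- function(rho = 0, alpha = 1, sigma2 = sqrt(7)) {
  two_patch_spec(a1 = 3, a2 = 4, d12 = alpha, d21 = alpha,
                 sigma1 = sqrt(7), sigma2 = sigma2, rho = rho)
}

# independent root-finding oracle for the proportion equilibrium
ystar_oracle <- function(a1, a2, d12, d21) {
  f <- function(y) (a1 - a2) * (1 - y) * y + d21 - (d12 + d21) * y
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# build a noise_path with prescribed increments (for coupling tests)
manual_noise <- function(increments, dt) {
  structure(list(times = seq(0, nrow(increments) * dt, by = dt),
                 increments = increments, dt = dt, seed = NA),
            class = "noise_path")
}

make_trajectory <- function(times, X, dt = diff(times[1:2])) {
  patchsde:::new_trajectory(times, X, seed = NA, scheme = "synthetic", dt = dt)
}
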