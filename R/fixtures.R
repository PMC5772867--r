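#' Named model fixtures
#'
#' A small catalog of parameterizations used throughout the examples and
#' tests:
#' \describe{
#'   \item{`two_patch_het`}{heterogeneous two-patch model, `a = (3, 4)`,
#'     `sigma1^2 = sigma2^2 = 7`, symmetric dispersal `d12 = d21 = alpha`
#'     and correlation `rho` both adjustable; the workhorse for studying
#'     `r` as a function of dispersal and noise correlation.}
#'   \item{`equal_sigma_degenerate`}{the same two patches driven by one
#'     shared Brownian motion (`rho = 1`, equal volatilities): the
#'     proportion process is noiseless and `r` has a closed form.}
#'   \item{`synchronized_slice`}{parameters satisfying
#'     `2 (d21 - d12) = a2 - a1` with equal competition and one shared
#'     Brownian motion, where the two abundances synchronize onto the
#'     diagonal; defaults give `r` of 1.5 (persistent).}
#'   \item{`single_patch`}{scalar logistic diffusion, `a = 3`,
#'     `sigma^2 = 7` (a sink with `r` of -0.5).}
#'   \item{`symmetric_n`}{`n` exchangeable patches (common growth rate,
#'     volatility, all-to-all dispersal), independent noise.}
#' }
#'
#' @return data frame listing fixture names and descriptions.
#' @export
fixture_catalog <- function() {
  data.frame(
    name = c("two_patch_het", "equal_sigma_degenerate", "synchronized_slice",
             "single_patch", "symmetric_n"),
    parameters = c("a1=3 a2=4 sigma^2=7 d12=d21=alpha rho adjustable",
                   "a1=3 a2=4 sigma^2=7 d12=d21=alpha rho=1",
                   "a1=a2=2 d12=d21=0.5 sigma^2=1 kappa=1 rho=1",
                   "a=3 sigma^2=7",
                   "n exchangeable patches, a=2 sigma^2=1 d=1 kappa=1"),
    exercises = c("growth rate vs dispersal/correlation",
                  "degenerate noise closed form",
                  "synchronization on the diagonal manifold",
                  "scalar trichotomy a - sigma^2/2",
                  "exchangeability / n > 2 Monte Carlo"),
    stringsAsFactors = FALSE)
}

#' Generate a named fixture model
#'
#' @param fixture one of the names in [fixture_catalog()].
#' @param ... overrides merged shallowly into the fixture's parameters
#'   (e.g. `rho = 0.5`, `alpha = 2`, `n = 4`), re-validated on build.
#' @return a `patch_model` (with the originating `two_patch_spec` attached
#'   where applicable).
#' @export
generate_fixture <- function(fixture, ...) {
  overrides <- list(...)
  known <- fixture_catalog()$name
  if (!fixture %in% known)
    stop("unknown fixture '", fixture, "'; available: ",
         paste(known, collapse = ", "))
  get_par <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  }
  switch(fixture,
    two_patch_het = {
      alpha <- get_par("alpha", 1)
      make_two_patch(two_patch_spec(
        a1 = get_par("a1", 3), a2 = get_par("a2", 4),
        comp1 = get_par("comp1", 1), comp2 = get_par("comp2", 1),
        d12 = get_par("d12", alpha), d21 = get_par("d21", alpha),
        sigma1 = get_par("sigma1", sqrt(7)),
        sigma2 = get_par("sigma2", sqrt(7)),
        rho = get_par("rho", 0)))
    },
    equal_sigma_degenerate = {
      alpha <- get_par("alpha", 1)
      sg <- get_par("sigma", sqrt(7))
      make_two_patch(two_patch_spec(
        a1 = get_par("a1", 3), a2 = get_par("a2", 4),
        comp1 = get_par("comp1", 1), comp2 = get_par("comp2", 1),
        d12 = alpha, d21 = alpha, sigma1 = sg, sigma2 = sg, rho = 1))
    },
    synchronized_slice = {
      a1 <- get_par("a1", 2)
      d12 <- get_par("d12", 0.5); d21 <- get_par("d21", 0.5)
      make_two_patch(two_patch_spec(
        a1 = a1, a2 = a1 + 2 * (d21 - d12),
        comp1 = get_par("comp", 1), comp2 = get_par("comp", 1),
        d12 = d12, d21 = d21,
        sigma1 = get_par("sigma", 1), sigma2 = get_par("sigma", 1),
        rho = 1))
    },
    single_patch = {
      patch_model(a = get_par("a", 3), competition = get_par("comp", 1),
                  D = matrix(0, 1, 1), sigma = sqrt(get_par("sigma_sq", 7)))
    },
    symmetric_n = {
      n <- get_par("n", 3)
      d <- get_par("d", 1)
      D <- matrix(d / (n - 1), n, n); diag(D) <- -d
      patch_model(a = rep(get_par("a", 2), n),
                  competition = rep(get_par("comp", 1), n), D = D,
                  sigma = rep(sqrt(get_par("sigma_sq", 1)), n),
                  rho = get_par("rho", 0))
    })
}
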