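#' Construct a patch population model
#'
#' Bundles the ingredients of the density-dependent patch SDE
#' \deqn{dX_i = \left(X_i (a_i - b_i(X_i)) + \sum_j D_{ji} X_j\right) dt
#'       + X_i \, dE_i(t),}
#' where `a` holds the per-capita growth rates at low density, `b` the
#' intraspecific competition functions (`b_i(0) = 0`), `D` the dispersal
#' matrix (nonnegative off-diagonal per-capita movement rates, zero row
#' sums), and the environmental noise is `E = Gamma^T B` for independent
#' standard Brownian motions `B`, with covariance `Sigma = Gamma^T Gamma`.
#'
#' @param a numeric vector of per-capita growth rates (1/time).
#' @param competition either a numeric vector `kappa` of linear competition
#'   coefficients (`b_i(x) = kappa_i x`), or a list of functions `b_i` with
#'   `b_i(0) = 0`.
#' @param D dispersal matrix (`n x n`), zero row sums, nonnegative
#'   off-diagonal entries.
#' @param Gamma noise loading matrix (`k x n`), one column per patch. Supply
#'   either `Gamma` or `sigma`/`rho`.
#' @param sigma per-patch volatilities (length `n`), used with `rho`.
#' @param rho common pairwise noise correlation in `[-1, 1]` (scalar), or an
#'   `n x n` correlation matrix.
#' @param validate if `TRUE` (default) the dispersal matrix is checked for
#'   irreducibility and an error is raised on failure.
#' @return An object of class `patch_model`: a list with elements `n`, `a`,
#'   `b` (list of functions), `kappa` (or `NULL` for non-linear
#'   competition), `D`, `Gamma`, `Sigma`, and `degenerate` (`TRUE` when
#'   `rank(Sigma) < n`).
#' @seealso [make_two_patch()], [from_growth_functions()],
#'   [check_competition()]
#' @export
patch_model <- function(a, competition, D, Gamma = NULL, sigma = NULL,
                        rho = 0, validate = TRUE) {
  a <- as.numeric(a)
  n <- length(a)
  stopifnot(n >= 1, all(is.finite(a)))
  D <- as.matrix(D)
  if (!is.numeric(D) || nrow(D) != n || ncol(D) != n || any(!is.finite(D)))
    stop("'D' must be a finite numeric ", n, "x", n, " matrix")
  rep <- validate_dispersal(D)
  if (validate && !rep$passed)
    stop("invalid dispersal matrix: ", rep$detail)

  if (is.numeric(competition)) {
    kappa <- as.numeric(competition)
    if (length(kappa) == 1L) kappa <- rep(kappa, n)
    stopifnot(length(kappa) == n)
    b <- lapply(kappa, function(k) local({ k0 <- k; function(x) k0 * x }))
  } else if (is.list(competition)) {
    b <- competition
    stopifnot(length(b) == n, all(vapply(b, is.function, logical(1))))
    kappa <- NULL
  } else stop("'competition' must be a kappa vector or a list of functions")
  b0 <- vapply(b, function(f) f(0), numeric(1))
  if (any(abs(b0) > 1e-12))
    stop("competition functions must vanish at 0; got b(0) = ",
         paste(signif(b0, 3), collapse = ", "))

  nz <- build_noise(sigma = sigma, rho = rho, Gamma = Gamma, n = n)

  structure(list(n = n, a = a, b = b, kappa = kappa, D = D,
                 Gamma = nz$Gamma, Sigma = nz$Sigma,
                 degenerate = nz$degenerate),
            class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat("Patch population model (", x$n, " patch",
      if (x$n > 1) "es", ")\n", sep = "")
  cat("  growth rates a: ", paste(signif(x$a, 4), collapse = ", "), "\n")
  cat("  competition:    ",
      if (!is.null(x$kappa)) paste0("linear, kappa = ",
                                    paste(signif(x$kappa, 4), collapse = ", "))
      else "custom functions", "\n")
  cat("  noise:          rank(Sigma) = ", qr(x$Sigma)$rank,
      if (x$degenerate) "  [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Validate a dispersal matrix
#'
#' A valid dispersal matrix has zero row sums, nonnegative off-diagonal
#' entries, and must be irreducible: the directed graph with an edge
#' `i -> j` whenever `D[i, j] > 0` (for `i != j`) is strongly connected, so
#' every patch is reachable from every other. Irreducibility is what makes
#' the proportion process mix over all patches.
#'
#' @param D a square numeric matrix.
#' @return An `assumption_report`: list with `assumption_id`, `passed`, and
#'   a `detail` string describing any violation.
#' @export
validate_dispersal <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("'D' must be a square numeric matrix")
  if (any(!is.finite(D))) stop("'D' contains non-finite entries")
  n <- nrow(D)
  problems <- character(0)
  off <- D; diag(off) <- 0
  if (any(off < 0))
    problems <- c(problems, sprintf("negative off-diagonal entries at %s",
      paste(which(off < 0, arr.ind = TRUE)[, 1], collapse = ",")))
  rs <- rowSums(D)
  bad <- which(abs(rs) > 1e-12)
  if (length(bad))
    problems <- c(problems, sprintf("row sums of rows %s are %s (must be 0)",
      paste(bad, collapse = ","), paste(signif(rs[bad], 3), collapse = ",")))
  if (!length(problems) && n > 1 && !strongly_connected(off > 0))
    problems <- c(problems, "positive-rate digraph is not strongly connected")
  assumption_report("irreducible_dispersal", length(problems) == 0L,
                    if (length(problems)) paste(problems, collapse = "; ")
                    else "zero row sums, nonnegative rates, strongly connected")
}

# strong connectivity of a logical adjacency matrix by double reachability
strongly_connected <- function(adj) {
  n <- nrow(adj)
  reach <- function(A, from) {
    seen <- logical(n); seen[from] <- TRUE
    frontier <- from
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  all(reach(adj, 1L)) && all(reach(t(adj), 1L))
}

assumption_report <- function(id, passed, detail, M_b = NA_real_,
                              gamma_b = NA_real_) {
  structure(list(assumption_id = id, passed = passed, detail = detail,
                 M_b = M_b, gamma_b = gamma_b),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", if (x$passed) "PASS" else "FAIL",
              x$assumption_id, x$detail))
  if (!is.na(x$M_b))
    cat(sprintf("  constants: M_b = %.4g, gamma_b = %.4g\n", x$M_b, x$gamma_b))
  invisible(x)
}

#' Build the environmental noise loading and covariance
#'
#' Either pass an explicit loading matrix `Gamma` (`k x n`, noise
#' `E = Gamma^T B` for `k` independent Brownian motions), or per-patch
#' volatilities `sigma` with a correlation `rho`. The covariance is
#' `Sigma = Gamma^T Gamma`; noise is flagged degenerate when
#' `rank(Sigma) < n` (singular values below `1e-10` times the largest),
#' e.g. all patches sharing one Brownian motion under perfect correlation.
#' For two patches with `rho = +/-1` the returned `Gamma` has a single row
#' (one driving Brownian motion).
#'
#' @inheritParams patch_model
#' @param n patch count (required when only `sigma` is scalar).
#' @return list with `Gamma`, `Sigma`, `degenerate`.
#' @export
build_noise <- function(sigma = NULL, rho = 0, Gamma = NULL, n = NULL) {
  if (is.null(Gamma)) {
    if (is.null(sigma)) stop("supply either 'Gamma' or 'sigma'")
    sigma <- as.numeric(sigma)
    if (!is.null(n) && length(sigma) == 1L) sigma <- rep(sigma, n)
    n <- length(sigma)
    if (any(sigma <= 0)) stop("volatilities must be positive")
    if (is.matrix(rho)) {
      R <- rho
      stopifnot(nrow(R) == n, ncol(R) == n, max(abs(R - t(R))) < 1e-12)
    } else {
      if (abs(rho) > 1) stop("|rho| must be <= 1")
      R <- matrix(rho, n, n); diag(R) <- 1
    }
    Sigma <- outer(sigma, sigma) * R
    if (n == 2 && !is.matrix(rho) && abs(abs(rho) - 1) < .Machine$double.eps * 4) {
      Gamma <- matrix(c(sigma[1], sign(rho) * sigma[2]), nrow = 1)
    } else {
      # loading via eigendecomposition, rows for non-null directions only
      e <- eigen(Sigma, symmetric = TRUE)
      pos <- e$values > 1e-10 * max(e$values)
      Gamma <- t(e$vectors[, pos, drop = FALSE] %*%
                   diag(sqrt(e$values[pos]), sum(pos)))
    }
  } else {
    Gamma <- as.matrix(Gamma)
    if (!is.null(n) && ncol(Gamma) != n)
      stop("'Gamma' must have one column per patch")
    n <- ncol(Gamma)
    Sigma <- crossprod(Gamma)
  }
  sv <- svd(Sigma, nu = 0, nv = 0)$d
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10 * max(sv)) stop("Sigma is not positive semidefinite")
  degenerate <- sum(sv > 1e-10 * max(sv)) < n
  list(Gamma = Gamma, Sigma = (Sigma + t(Sigma)) / 2, degenerate = degenerate)
}

#' Split per-capita growth functions into growth rates and competition
#'
#' A model given through per-capita growth functions `f_i(x)` is rewritten
#' in growth/competition form via `a_i = f_i(0)` and
#' `b_i(x) = f_i(0) - f_i(x)`, so `b_i(0) = 0` by construction and
#' `f_i(x) = a_i - b_i(x)` is an identity.
#'
#' @param f list of per-capita growth functions, one per patch.
#' @return list with numeric `a` and list `b` of competition functions.
#' @export
from_growth_functions <- function(f) {
  stopifnot(is.list(f), all(vapply(f, is.function, logical(1))))
  a <- vapply(f, function(fi) {
    v <- tryCatch(fi(0), error = function(e)
      stop("growth function not evaluable at 0: ", conditionMessage(e)))
    as.numeric(v)
  }, numeric(1))
  b <- mapply(function(fi, ai) {
    force(fi); force(ai)
    function(x) ai - fi(x)
  }, f, a, SIMPLIFY = FALSE)
  list(a = a, b = b)
}

#' Check the competition admissibility condition
#'
#' Persistence theory requires the competition terms to eventually dominate
#' growth: there must be constants `M_b`, `gamma_b > 0` such that
#' \deqn{\frac{\sum_i x_i (b_i(x_i) - a_i)}{\sum_i x_i} > \gamma_b
#'       \quad \text{whenever } \sum_i x_i \ge M_b.}
#' For linear competition `b_i(x) = kappa_i x` with all `kappa_i > 0` the
#' condition always holds and analytic constants are returned. Otherwise a
#' per-patch sufficient condition (`inf_{x >= M} b_i(x) - a_i > gamma_b`)
#' is searched on a grid; since the condition quantifies over an unbounded
#' set, failure to find a bound below `grid_max` is reported as
#' inconclusive rather than as a definitive failure.
#'
#' @param model a `patch_model`.
#' @param grid_max largest abundance scanned for the bound.
#' @param grid_n number of grid points.
#' @return An `assumption_report` carrying `M_b` and `gamma_b` when found.
#' @export
check_competition <- function(model, grid_max = 1e4, grid_n = 2048) {
  stopifnot(inherits(model, "patch_model"), grid_max > 0)
  a <- model$a
  if (!is.null(model$kappa)) {
    if (all(model$kappa > 0)) {
      gamma_b <- 1
      M_b <- model$n * (1 + max(a, 0) + gamma_b) / min(model$kappa)
      return(assumption_report("competition_growth_bound", TRUE,
        "linear competition with positive coefficients (analytic bound)",
        M_b = M_b, gamma_b = gamma_b))
    }
    return(assumption_report("competition_growth_bound", FALSE,
      "linear competition with a nonpositive coefficient"))
  }
  # grid search on the per-patch sufficient condition
  xs <- seq(0, grid_max, length.out = grid_n)[-1]
  B <- vapply(model$b, function(f) vapply(xs, f, numeric(1)), numeric(length(xs)))
  # running infimum from the right: inf_{x >= M} b_i(x) computed per patch
  for (gamma_b in c(1, 0.1, 0.01)) {
    ok <- rep(NA_real_, model$n)
    for (i in seq_len(model$n)) {
      tail_inf <- rev(cummin(rev(B[, i])))
      idx <- which(tail_inf - a[i] > gamma_b)
      ok[i] <- if (length(idx)) xs[min(idx)] else NA_real_
    }
    if (!anyNA(ok))
      return(assumption_report("competition_growth_bound", TRUE,
        sprintf("grid bound attained (gamma_b = %g)", gamma_b),
        M_b = max(ok), gamma_b = gamma_b))
  }
  assumption_report("competition_growth_bound", FALSE,
                    sprintf("inconclusive up to grid_max = %g", grid_max))
}

#' Two-patch model specification
#'
#' Convenience container for the fully worked two-patch case: growth rates
#' `a1`, `a2`, linear competition coefficients `comp1`, `comp2`, dispersal
#' rates `d12` (patch 1 to patch 2) and `d21` (patch 2 to patch 1),
#' per-patch volatilities `sigma1`, `sigma2`, and the inter-patch noise
#' correlation `rho`. `rho = +/-1` gives the degenerate case where a single
#' Brownian motion drives both patches.
#'
#' @param a1,a2 per-capita growth rates.
#' @param comp1,comp2 linear competition coefficients (> 0).
#' @param d12,d21 dispersal rates (>= 0).
#' @param sigma1,sigma2 volatilities (> 0).
#' @param rho correlation in `[-1, 1]`.
#' @return object of class `two_patch_spec`.
#' @export
two_patch_spec <- function(a1, a2, comp1 = 1, comp2 = 1, d12, d21,
                           sigma1, sigma2, rho = 0) {
  stopifnot(d12 >= 0, d21 >= 0, abs(rho) <= 1, sigma1 > 0, sigma2 > 0)
  structure(list(a1 = a1, a2 = a2, comp1 = comp1, comp2 = comp2,
                 d12 = d12, d21 = d21, sigma1 = sigma1, sigma2 = sigma2,
                 rho = rho),
            class = "two_patch_spec")
}

#' @export
print.two_patch_spec <- function(x, ...) {
  cat(sprintf(paste0("Two-patch spec: a = (%g, %g), kappa = (%g, %g), ",
                     "d12 = %g, d21 = %g, sigma^2 = (%g, %g), rho = %g\n"),
              x$a1, x$a2, x$comp1, x$comp2, x$d12, x$d21,
              x$sigma1^2, x$sigma2^2, x$rho))
  invisible(x)
}

#' Build a patch model from a two-patch specification
#'
#' @param spec a [two_patch_spec()].
#' @return a validated two-patch `patch_model` carrying the spec as
#'   attribute `"spec"`.
#' @export
make_two_patch <- function(spec) {
  stopifnot(inherits(spec, "two_patch_spec"))
  D <- matrix(c(-spec$d12, spec$d12, spec$d21, -spec$d21),
              nrow = 2, byrow = TRUE)
  m <- patch_model(a = c(spec$a1, spec$a2),
                   competition = c(spec$comp1, spec$comp2), D = D,
                   sigma = c(spec$sigma1, spec$sigma2), rho = spec$rho)
  attr(m, "spec") <- spec
  m
}

# Recover a two_patch_spec from an n = 2 linear-competition model.
as_two_patch_spec <- function(model) {
  sp <- attr(model, "spec")
  if (!is.null(sp)) return(sp)
  stopifnot(inherits(model, "patch_model"), model$n == 2)
  if (is.null(model$kappa))
    stop("two-patch spec recovery needs linear competition")
  s1 <- sqrt(model$Sigma[1, 1]); s2 <- sqrt(model$Sigma[2, 2])
  two_patch_spec(a1 = model$a[1], a2 = model$a[2],
                 comp1 = model$kappa[1], comp2 = model$kappa[2],
                 d12 = model$D[1, 2], d21 = model$D[2, 1],
                 sigma1 = s1, sigma2 = s2,
                 rho = model$Sigma[1, 2] / (s1 * s2))
}
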