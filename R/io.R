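#' Write a patch model to JSON
#'
#' The on-disk schema is
#' `{n, a, competition: {type: "linear", kappa} , D, noise: {type:
#' "volatility_correlation", sigma, rho} | {type: "loading", Gamma}}`.
#' Numbers are serialized with full precision so a load/dump/load round
#' trip is exact. Models with non-linear (function) competition cannot be
#' serialized.
#'
#' @param model a `patch_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "patch_model"))
  if (is.null(model$kappa))
    stop("only linear-competition models can be serialized")
  doc <- list(n = model$n, a = model$a,
              competition = list(type = "linear", kappa = model$kappa),
              D = model$D,
              noise = list(type = "loading", Gamma = model$Gamma))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

model_schema <- list(
  top = c("n", "a", "competition", "D", "noise"),
  competition = c("type", "kappa"),
  noise = c("type", "sigma", "rho", "Gamma"))

#' Read a patch model from JSON
#'
#' Validates the document against the model schema (unknown keys are
#' rejected) and rebuilds the model through the standard constructors, so
#' all invariants are re-checked.
#'
#' @param path JSON file written by [write_model_json()] or by hand.
#' @return a `patch_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
  check_keys(doc, model_schema$top, "model document")
  check_keys(doc$competition, model_schema$competition, "competition")
  check_keys(doc$noise, model_schema$noise, "noise")
  if (!identical(doc$competition$type, "linear"))
    stop("unsupported competition type: ", doc$competition$type)
  D <- matrix(unlist(doc$D), nrow = doc$n, byrow = is.list(doc$D))
  if (is.matrix(doc$D)) D <- doc$D
  if (identical(doc$noise$type, "loading")) {
    G <- doc$noise$Gamma
    if (!is.matrix(G)) G <- matrix(unlist(G), ncol = doc$n, byrow = TRUE)
    patch_model(a = doc$a, competition = doc$competition$kappa, D = D,
                Gamma = G)
  } else if (identical(doc$noise$type, "volatility_correlation")) {
    patch_model(a = doc$a, competition = doc$competition$kappa, D = D,
                sigma = doc$noise$sigma, rho = doc$noise$rho)
  } else stop("unsupported noise type: ", doc$noise$type)
}

#' Write a trajectory to CSV
#'
#' Columns `t, X1..Xn, S, Y1..Yn`. A JSON sidecar `<path>.json` records
#' the seed, step size and scheme for provenance.
#'
#' @param traj a `patch_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "patch_trajectory"))
  n <- ncol(traj$X)
  df <- data.frame(t = traj$times, traj$X, S = traj$S, traj$Y)
  names(df) <- c("t", paste0("X", seq_len(n)), "S", paste0("Y", seq_len(n)))
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(list(seed = traj$seed, dt = traj$dt,
                              scheme = traj$scheme, points = nrow(traj$X)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectory_csv()].
#' @return a `patch_trajectory` (seed/scheme restored from the sidecar
#'   when present).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- sum(grepl("^X", names(df)))
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(seed = NA, dt = NA, scheme = "unknown")
  new_trajectory(df$t, as.matrix(df[paste0("X", seq_len(n))]),
                 meta$seed, meta$scheme, meta$dt)
}

#' Command-line interface
#'
#' Thin subcommand dispatcher over the package functions, used by the
#' `inst/cli/patchsde` script. Subcommands: `fixtures` (list the catalog),
#' `simulate` (write a trajectory CSV), `growth-rate` (print a JSON
#' result), `classify` (persistence verdict), `scan` (sweep dispersal and
#' correlation grids into a tidy CSV), `diagnose` (occupation fractions
#' and slopes for a trajectory CSV). Outputs are deterministic given
#' `--seed`.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 on success, 1 on validation failure, 2 on
#'   usage error.
#' @export
run_cli <- function(argv = character()) {
  usage <- paste(
    "usage: patchsde <subcommand> [options]",
    "  fixtures --list",
    "  simulate --fixture NAME [--rho R --alpha A] --x0 v1,v2 --T T [--dt DT] [--seed S] --out FILE",
    "  growth-rate (--fixture NAME [--rho R --alpha A] | --model FILE) [--method M] [--seed S]",
    "  classify   (--fixture NAME [--rho R --alpha A] | --model FILE) [--tolerance TOL] [--seed S]",
    "  scan --fixture NAME --alpha-grid lo:hi:n[:log] --rho-grid r1,r2,... --out FILE [--seed S]",
    "  diagnose --trajectory FILE [--eta e1,e2,...]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  sub <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  if (is.null(opts)) { message(usage); return(2L) }

  res <- tryCatch(switch(sub,
    "fixtures" = { print(fixture_catalog()); 0L },
    "simulate" = cli_simulate(opts),
    "growth-rate" = cli_growth_rate(opts),
    "classify" = cli_classify(opts),
    "scan" = cli_scan(opts),
    "diagnose" = cli_diagnose(opts),
    { message("unknown subcommand: ", sub); message(usage); 2L }),
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  res
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2L
    }
  }
  opts
}

cli_model_from_opts <- function(opts) {
  if (!is.null(opts$model)) return(read_model_json(opts$model))
  if (is.null(opts$fixture)) stop("supply --fixture or --model")
  ov <- list(fixture = opts$fixture)
  for (k in c("rho", "alpha", "a1", "a2", "sigma_sq", "n"))
    if (!is.null(opts[[k]])) ov[[k]] <- as.numeric(opts[[k]])
  do.call(generate_fixture, ov)
}

cli_simulate <- function(opts) {
  model <- cli_model_from_opts(opts)
  x0 <- as.numeric(strsplit(opts$x0 %||% "1", ",")[[1]])
  if (length(x0) == 1) x0 <- rep(x0, model$n)
  traj <- simulate_X(model, x0, T = as.numeric(opts[["T"]] %||% 100),
                     dt = as.numeric(opts$dt %||% 1e-3),
                     seed = as.integer(opts$seed %||% 1))
  write_trajectory_csv(traj, opts$out %||% stop("--out required"))
  0L
}

cli_growth_rate <- function(opts) {
  model <- cli_model_from_opts(opts)
  res <- stochastic_growth_rate(model, method = opts$method %||% "auto",
                                seed = as.integer(opts$seed %||% 1))
  cat(jsonlite::toJSON(list(r = res$r, se = res$se, method = res$method),
                       auto_unbox = TRUE, digits = NA), "\n")
  0L
}

cli_classify <- function(opts) {
  model <- cli_model_from_opts(opts)
  res <- stochastic_growth_rate(model, seed = as.integer(opts$seed %||% 1))
  cls <- classify_persistence(res,
                              tolerance = as.numeric(opts$tolerance %||% 1e-3))
  cat(jsonlite::toJSON(list(verdict = cls$verdict, r = res$r, se = res$se,
                            tolerance = cls$tolerance),
                       auto_unbox = TRUE, digits = NA), "\n")
  0L
}

cli_scan <- function(opts) {
  stopifnot(!is.null(opts$fixture), !is.null(opts$out))
  ag <- strsplit(opts[["alpha-grid"]] %||% "0.5:16:6:log", ":")[[1]]
  lo <- as.numeric(ag[1]); hi <- as.numeric(ag[2])
  npts <- as.integer(ag[3])
  alphas <- if (length(ag) > 3 && ag[4] == "log")
    exp(seq(log(lo), log(hi), length.out = npts))
  else seq(lo, hi, length.out = npts)
  rhos <- as.numeric(strsplit(opts[["rho-grid"]] %||% "0,1", ",")[[1]])
  seed <- as.integer(opts$seed %||% 1)
  rows <- do.call(rbind, lapply(rhos, function(rho) {
    do.call(rbind, lapply(alphas, function(al) {
      m <- generate_fixture(opts$fixture, alpha = al, rho = rho)
      res <- stochastic_growth_rate(m, seed = seed)
      cls <- classify_persistence(res)
      data.frame(d = al, rho = rho, r = res$r, se = res$se,
                 method = res$method, verdict = cls$verdict)
    }))
  }))
  utils::write.csv(rows, opts$out, row.names = FALSE)
  0L
}

cli_diagnose <- function(opts) {
  stopifnot(!is.null(opts$trajectory))
  traj <- read_trajectory_csv(opts$trajectory)
  etas <- as.numeric(strsplit(opts$eta %||% "0.001,0.01,0.1", ",")[[1]])
  occ <- lapply(etas, function(e) occupation_fraction(traj, e))
  slopes <- tryCatch(extinction_slopes(traj), error = function(e) NULL)
  out <- list(occupation = lapply(occ, function(o)
                list(eta = o$eta, fraction = o$fraction)),
              slopes = if (!is.null(slopes)) slopes$slopes,
              slope_spread = if (!is.null(slopes)) slopes$spread)
  cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null"),
      "\n")
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
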