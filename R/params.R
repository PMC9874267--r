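#' Construct a host-pathogen parameter set
#'
#' Builds a one-row tibble holding the ecological and trade-off parameters of
#' the age-structured susceptible-infected model, together with the trade-off
#' wiring (which life-history trait each resistance trait degrades) and the
#' resident resistance traits. All downstream functions
#' ([r0()], [endemic_equilibrium()], [find_cosingular()], [run_sweep()], ...)
#' take this tibble as their first argument, so parameter sets chain naturally
#' with the pipe and can be row-bound into sweep grids.
#'
#' The model tracks susceptible and infected juveniles and adults
#' (`SJ`, `SA`, `IJ`, `IA`). Juveniles mature at rate `g`, adults reproduce at
#' density-dependent rate `a(1 - qN)`, all hosts die naturally at stage
#' mortality rates `bJ`, `bA`, and transmission is density-dependent with
#' stage transmission rate `beta0 * (1 - r_i)` where `r_i` is resistance at
#' stage `i`. Infection either reduces fecundity by a factor `f` (sterility
#' virulence `1 - f`) or adds mortality `alpha` (mortality virulence); the
#' headline analyses use one virulence type at a time. There is no recovery.
#'
#' @param a0 Baseline adult reproduction rate (per unit time). Default 5.
#' @param b0 Baseline natural mortality rate, shared by both stages. Default 1
#'   (time is rescaled so that `b0 = 1` without loss of generality).
#' @param g0 Baseline maturation rate. Default 1.
#' @param q Strength of density dependence (per density). Default 1 (density
#'   is rescaled so that `q = 1` without loss of generality).
#' @param beta0 Baseline transmission rate (per density per time). Default 8.
#' @param f Fecundity retained when infected, in `[0, 1]`; sterility virulence
#'   is `1 - f`. Default 1 (no sterility virulence).
#' @param alpha Mortality virulence rate (additional death rate of infected
#'   hosts), non-negative. Default 0.
#' @param c1J,c1A Trade-off strengths in `(0, 1]`: maximum proportional change
#'   of the costed life-history trait at full resistance. `c1 = 0` disables
#'   the trade-off. Default 0.5.
#' @param c2J,c2A Trade-off curvatures; positive values give accelerating
#'   costs (diminishing returns of resistance). Default 3.
#' @param juvenile_target Life-history trait degraded by juvenile resistance:
#'   one of `"maturation"`, `"reproduction"`, `"juvenile_mortality"`.
#' @param adult_target Life-history trait degraded by adult resistance: one of
#'   `"reproduction"`, `"adult_mortality"`.
#' @param rJ,rA Resident resistance traits in `[0, 1]` (0 = fully
#'   susceptible, 1 = fully resistant). Default 0.
#'
#' @return A one-row tibble with class `host_params`.
#' @examples
#' host_params(beta0 = 8, f = 0.1) |> r0()
#' @export
host_params <- function(a0 = 5, b0 = 1, g0 = 1, q = 1, beta0 = 8,
                        f = 1, alpha = 0,
                        c1J = 0.5, c2J = 3, c1A = 0.5, c2A = 3,
                        juvenile_target = c("maturation", "reproduction",
                                            "juvenile_mortality"),
                        adult_target = c("reproduction", "adult_mortality"),
                        rJ = 0, rA = 0) {
  juvenile_target <- match.arg(juvenile_target)
  adult_target <- match.arg(adult_target)
  out <- tibble::tibble(
    a0 = a0, b0 = b0, g0 = g0, q = q, beta0 = beta0, f = f, alpha = alpha,
    c1J = c1J, c2J = c2J, c1A = c1A, c2A = c2A,
    juvenile_target = juvenile_target, adult_target = adult_target,
    rJ = rJ, rA = rA)
  validate_params(out)
  class(out) <- c("host_params", class(out))
  out
}

param_fields <- c("a0", "b0", "g0", "q", "beta0", "f", "alpha",
                  "c1J", "c2J", "c1A", "c2A",
                  "juvenile_target", "adult_target", "rJ", "rA")

#' Validate a parameter table
#'
#' Checks the invariants of the model parameters: non-negative rates,
#' `f` in `[0, 1]`, trade-off strengths in `[0, 1]`, resistance traits in
#' `[0, 1]`, and recognised trade-off wiring. Called internally by every
#' user-facing function; exported for use on hand-built tables.
#'
#' @param params A data frame with the columns of [host_params()].
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  missing <- setdiff(param_fields, names(params))
  if (length(missing) > 0) {
    abort(paste0("missing parameter column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ageresist_param_error")
  }
  chk <- function(ok, what) {
    if (!all(ok)) {
      abort(paste0("invalid parameter value(s): ", what),
            class = "ageresist_param_error")
    }
  }
  num <- c("a0", "b0", "g0", "q", "beta0", "alpha")
  for (v in num) chk(is.numeric(params[[v]]) & params[[v]] >= 0 &
                       is.finite(params[[v]]),
                     paste(v, "must be a finite non-negative number"))
  chk(params$f >= 0 & params$f <= 1, "f must lie in [0, 1]")
  for (v in c("c1J", "c1A")) {
    chk(params[[v]] >= 0 & params[[v]] <= 1,
        paste(v, "must lie in [0, 1]"))
  }
  for (v in c("rJ", "rA")) {
    chk(params[[v]] >= 0 & params[[v]] <= 1,
        paste(v, "must lie in [0, 1]"))
  }
  chk(params$juvenile_target %in%
        c("maturation", "reproduction", "juvenile_mortality"),
      "juvenile_target must be maturation, reproduction or juvenile_mortality")
  chk(params$adult_target %in% c("reproduction", "adult_mortality"),
      "adult_target must be reproduction or adult_mortality")
  invisible(params)
}

# Extract row i of a parameter table as a plain list (fast internal currency).
plist <- function(params, i = 1) {
  p <- as.list(params[i, param_fields, drop = FALSE])
  p
}

#' Read a parameter set from a configuration file
#'
#' Reads a flat key-value YAML or JSON file whose keys are the arguments of
#' [host_params()] (`a0`, `b0`, `g0`, `q`, `beta0`, `f`, `alpha`, `c1J`,
#' `c2J`, `c1A`, `c2A`, `juvenile_target`, `adult_target`, `rJ`, `rA`).
#' Missing keys take the [host_params()] defaults; unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `host_params` tibble.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "ageresist_config_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) {
    abort("config must be a flat key-value mapping",
          class = "ageresist_config_error")
  }
  unknown <- setdiff(names(cfg), param_fields)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ageresist_config_error")
  }
  do.call(host_params, cfg)
}

#' Draw random viable parameter sets
#'
#' Samples parameter tables for property-based validation: baseline rates,
#' virulence, trade-off shapes, wiring and resident traits are drawn uniformly
#' from broad ranges, then filtered so that the host is viable and (optionally)
#' the disease is endemic at the resident traits. One virulence type is active
#' per draw (sterility or mortality), matching the model's headline analyses.
#'
#' @param n Number of parameter rows to return.
#' @param seed Optional integer seed for reproducibility.
#' @param endemic_only Keep only draws with `R0 > 1` at the resident traits
#'   (default `TRUE`).
#' @param max_resistance Upper bound for the sampled resident traits; keeping
#'   it below 1 leaves room for mutants on both sides. Default 0.9.
#' @return A `host_params` tibble with `n` rows.
#' @export
sample_params <- function(n, seed = NULL, endemic_only = TRUE,
                          max_resistance = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function() {
    sterility <- runif(1) < 0.5
    host_params(
      a0 = runif(1, 2, 10), b0 = 1, g0 = runif(1, 0.5, 2), q = 1,
      beta0 = runif(1, 2, 30),
      f = if (sterility) runif(1) else 1,
      alpha = if (sterility) 0 else runif(1, 0, 2),
      c1J = runif(1, 0.1, 1), c2J = runif(1, 0.5, 6),
      c1A = runif(1, 0.1, 1), c2A = runif(1, 0.5, 6),
      juvenile_target = sample(c("maturation", "reproduction",
                                 "juvenile_mortality"), 1),
      adult_target = sample(c("reproduction", "adult_mortality"), 1),
      rJ = runif(1, 0, max_resistance), rA = runif(1, 0, max_resistance))
  }
  rows <- vector("list", n)
  k <- 0
  tries <- 0
  while (k < n && tries < 200 * n) {
    tries <- tries + 1
    p <- draw1()
    pl <- plist(p)
    e <- effective_rates_list(pl)
    if (!host_viable(e)) next
    if (endemic_only && r0_closed(pl, e) <= 1.05) next
    k <- k + 1
    rows[[k]] <- p
  }
  if (k < n) {
    abort("rejection sampling failed to find enough viable parameter sets",
          class = "ageresist_param_error")
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("host_params", class(out))
  out
}
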