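# Parameter-sweep drivers: track singular strategies and resident densities
# along a parameter grid, and detect regions of evolutionary bistability.

#' Sweep a parameter and track the singular strategies
#'
#' For each value of the swept parameter, finds the singular resistance
#' strategies ([find_cosingular()]) and records, per attractor, the resident
#' endemic densities (total and infected). In `"continuation"` mode the
#' interior attractors found at the previous grid point seed the root search
#' at the next (with a coarse sign grid still scanned for new branches); in
#' `"global"` mode every point gets the full multistart. Per-point solver
#' failures are recorded (`status = "failed"`) and the sweep continues.
#'
#' @param params A one-row `host_params` tibble of fixed parameters.
#' @param param Name of the swept parameter: any numeric [host_params()]
#'   field (e.g. `"f"`, `"alpha"`, `"beta0"`).
#' @param values Strictly monotone numeric grid of values to sweep.
#' @param mode `"continuation"` or `"global"`.
#' @param grid_n Sign-grid resolution for the multistart (default 6 in
#'   global mode, 4 in continuation mode).
#' @return A tibble of class `sweep_result`, one row per grid point per
#'   singular strategy: the swept value, `rJ_star`, `rA_star`,
#'   `classification`, `attractor`, `N_star`, `I_star`, `R0`, `host_viable`,
#'   `disease_present`, `status`.
#' @examples
#' \donttest{
#' host_params(beta0 = 8, alpha = 0,
#'             juvenile_target = "juvenile_mortality",
#'             adult_target = "reproduction") |>
#'   run_sweep("f", c(0.9, 0.5, 0.1))
#' }
#' @export
run_sweep <- function(params, param, values,
                      mode = c("continuation", "global"), grid_n = NULL) {
  validate_params(params)
  mode <- match.arg(mode)
  if (!param %in% setdiff(param_fields,
                          c("juvenile_target", "adult_target"))) {
    abort(paste0("unknown sweep parameter: ", param),
          class = "ageresist_config_error")
  }
  if (length(values) > 1 && !(all(diff(values) > 0) ||
                              all(diff(values) < 0))) {
    abort("sweep values must be strictly monotone",
          class = "ageresist_config_error")
  }
  grid_n <- grid_n %||% if (mode == "global") 6 else 4
  prev_starts <- NULL
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    params_i <- as_tibble(params)[1, ]
    params_i[[param]] <- values[i]
    res <- tryCatch({
      p <- plist(params_i)
      e <- effective_rates_list(p)
      viable <- host_viable(e)
      base <- tibble(value = values[i], host_viable = viable)
      if (!viable) {
        dplyr::bind_cols(base,
                         tibble(rJ_star = NA_real_, rA_star = NA_real_,
                                classification = "host-extinct",
                                attractor = NA, N_star = 0, I_star = 0,
                                R0 = NA_real_, disease_present = FALSE,
                                status = "ok"))
      } else {
        sing <- find_cosingular(params_i,
                                starts = if (mode == "continuation")
                                  prev_starts else NULL,
                                grid_n = grid_n)
        if (nrow(sing) == 0) {
          dplyr::bind_cols(base,
                           tibble(rJ_star = NA_real_, rA_star = NA_real_,
                                  classification = "none-found",
                                  attractor = NA, N_star = NA_real_,
                                  I_star = NA_real_, R0 = NA_real_,
                                  disease_present = NA, status = "ok"))
        } else {
          prev_int <- sing[sing$boundary == "none", c("rJ_star", "rA_star")]
          if (mode == "continuation" && nrow(prev_int) > 0) {
            prev_starts <- as.matrix(prev_int)
          }
          dplyr::bind_cols(
            base[rep(1, nrow(sing)), ],
            dplyr::mutate(
              sing[, c("rJ_star", "rA_star", "classification", "attractor",
                       "N_star", "I_star", "R0")],
              disease_present = .data$I_star > 1e-8, status = "ok"))
        }
      }
    }, error = function(err) {
      tibble(value = values[i], host_viable = NA, rJ_star = NA_real_,
             rA_star = NA_real_, classification = NA_character_,
             attractor = NA, N_star = NA_real_, I_star = NA_real_,
             R0 = NA_real_, disease_present = NA,
             status = paste0("failed: ", conditionMessage(err)))
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "value"] <- param
  attr(out, "swept_param") <- param
  attr(out, "params") <- as_tibble(params)[1, ]
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  NextMethod()
  invisible(x)
}

#' @describeIn run_sweep `autoplot()` draws the attractor resistance levels
#'   (juvenile solid red, adult dashed blue) and the resident total (dotted
#'   grey) and infected (solid grey) densities against the swept parameter.
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  param <- attr(object, "swept_param")
  d <- object |>
    dplyr::filter(.data$attractor %in% TRUE) |>
    dplyr::rename(x = dplyr::all_of(param))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$N_star), colour = "grey60",
                       linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$I_star), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rJ_star), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rA_star), colour = "blue",
                        shape = 1) +
    ggplot2::labs(x = param,
                  y = "resistance (red = juvenile, blue = adult) / density")
}

#' Detect bistability along a parameter sweep
#'
#' Runs a global-multistart sweep and reports, per grid value, the number of
#' evolutionary attractors, whether the point is bistable (at least two), and
#' whether any pair of coexisting attractors is stage-divergent (one stage's
#' resistance much higher in one attractor while the other stage's resistance
#' is higher in the other). Maximal runs of bistable grid points are returned
#' as regions.
#'
#' @inheritParams run_sweep
#' @param divergence_margin Minimum opposite-direction difference per trait
#'   for a pair of attractors to count as stage-divergent (default 0.2).
#' @return A list with `by_value` (tibble: value, `n_attractors`, `bistable`,
#'   `divergent_stages`), `regions` (tibble of bistable runs with start/end
#'   values) and the underlying `sweep` result.
#' @export
detect_bistability <- function(params, param, values, grid_n = 6,
                               divergence_margin = 0.2) {
  sweep <- run_sweep(params, param, values, mode = "global", grid_n = grid_n)
  vals <- sweep[[param]]
  by_value <- purrr::map(unique(vals), function(v) {
    d <- sweep[vals == v & sweep$attractor %in% TRUE, , drop = FALSE]
    divergent <- FALSE
    if (nrow(d) >= 2) {
      for (i in seq_len(nrow(d) - 1)) {
        for (j in seq(i + 1, nrow(d))) {
          dJ <- d$rJ_star[i] - d$rJ_star[j]
          dA <- d$rA_star[i] - d$rA_star[j]
          if (dJ * dA < 0 && abs(dJ) > divergence_margin &&
              abs(dA) > divergence_margin) {
            divergent <- TRUE
          }
        }
      }
    }
    tibble(value = v, n_attractors = nrow(d), bistable = nrow(d) >= 2,
           divergent_stages = divergent)
  }) |> dplyr::bind_rows()
  r <- rle(by_value$bistable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- tibble(start = by_value$value[starts[r$values]],
                    end = by_value$value[ends[r$values]])
  names(by_value)[1] <- param
  list(by_value = by_value, regions = regions, sweep = sweep)
}
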