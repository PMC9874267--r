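# Stochastic trait-substitution simulation: repeated introduction of
# adjacent-phenotype mutants into the multi-phenotype ecological dynamics,
# relaxing the rare-mutation / small-mutation assumptions of the invasion
# analysis.

# vectorised RHS for k phenotypes sharing density dependence (q N over all
# phenotypes) and force of infection (sum of infecteds over all phenotypes)
multi_rhs <- function(y, k, rates, p) {
  dim(y) <- c(k, 4)
  N <- sum(y)
  It <- sum(y[, 3], y[, 4])
  lJ <- rates$betaJ * It
  lA <- rates$betaA * It
  birth <- rates$a * (1 - p$q * N) * (y[, 2] + p$f * y[, 4])
  d <- cbind(
    birth - (rates$bJ + rates$g + lJ) * y[, 1],
    rates$g * y[, 1] - (rates$bA + lA) * y[, 2],
    lJ * y[, 1] - (rates$bJ + rates$g + p$alpha) * y[, 3],
    rates$g * y[, 3] + lA * y[, 2] - (rates$bA + p$alpha) * y[, 4])
  dim(d) <- NULL
  d
}

# analytic Jacobian of the stacked multi-phenotype system (dense: all
# phenotypes couple through N and the shared force of infection)
multi_jac <- function(y, k, rates, p) {
  dim(y) <- c(k, 4)
  N <- sum(y)
  It <- sum(y[, 3], y[, 4])
  ones <- rep(1, 4 * k)
  rp <- y[, 2] + p$f * y[, 4]            # reproductive pool per phenotype
  a1 <- rates$a * (1 - p$q * N)
  J <- matrix(0, 4 * k, 4 * k)
  iSJ <- seq_len(k)
  iSA <- k + iSJ
  iIJ <- 2 * k + iSJ
  iIA <- 3 * k + iSJ
  # SJ rows
  J[iSJ, ] <- (-p$q * rates$a * rp) %o% ones
  J[iSJ, c(iIJ, iIA)] <- J[iSJ, c(iIJ, iIA)] -
    (rates$betaJ * y[, 1]) %o% rep(1, 2 * k)
  J[cbind(iSJ, iSJ)] <- J[cbind(iSJ, iSJ)] -
    (rates$bJ + rates$g + rates$betaJ * It)
  J[cbind(iSJ, iSA)] <- J[cbind(iSJ, iSA)] + a1
  J[cbind(iSJ, iIA)] <- J[cbind(iSJ, iIA)] + a1 * p$f
  # SA rows
  J[iSA, c(iIJ, iIA)] <- -(rates$betaA * y[, 2]) %o% rep(1, 2 * k)
  J[cbind(iSA, iSJ)] <- rates$g
  J[cbind(iSA, iSA)] <- -(rates$bA + rates$betaA * It)
  # IJ rows
  J[iIJ, c(iIJ, iIA)] <- (rates$betaJ * y[, 1]) %o% rep(1, 2 * k)
  J[cbind(iIJ, iSJ)] <- rates$betaJ * It
  J[cbind(iIJ, iIJ)] <- J[cbind(iIJ, iIJ)] -
    (rates$bJ + rates$g + p$alpha)
  # IA rows
  J[iIA, c(iIJ, iIA)] <- (rates$betaA * y[, 2]) %o% rep(1, 2 * k)
  J[cbind(iIA, iSA)] <- rates$betaA * It
  J[cbind(iIA, iIJ)] <- J[cbind(iIA, iIJ)] + rates$g
  J[cbind(iIA, iIA)] <- J[cbind(iIA, iIA)] - (rates$bA + p$alpha)
  J
}

phen_rates <- function(p, phen) {
  k <- nrow(phen)
  out <- list(a = numeric(k), g = numeric(k), bJ = numeric(k),
              bA = numeric(k), betaJ = numeric(k), betaA = numeric(k))
  for (i in seq_len(k)) {
    e <- effective_rates_list(p, phen[i, 1], phen[i, 2])
    for (nm in names(out)) out[[nm]][i] <- e[[nm]]
  }
  out
}

#' Trait-substitution evolutionary simulation
#'
#' Simulates the joint evolution of juvenile and adult resistance on a
#' discrete trait grid. Each event (1) integrates the multi-phenotype
#' ecological dynamics for a fixed window, (2) removes phenotypes whose total
#' density has fallen below the extinction threshold, and (3) introduces one
#' mutant at low density: a parent phenotype is chosen with probability
#' proportional to its birth output `a (1 - qN)(SA + f IA)`, one of its two
#' traits is perturbed by one grid step (random sign, reflecting at the trait
#' boundaries), and the mutant enters the susceptible juvenile class.
#' The run is deterministic given `seed`.
#'
#' @param params A one-row `host_params` tibble.
#' @param rJ_init,rA_init Initial (monomorphic) traits; rounded to the grid.
#' @param n_events Number of mutation events (default 400).
#' @param seed Integer seed for the mutation lottery.
#' @param step Trait grid step (default 0.02, i.e. 51 phenotypes per trait;
#'   the grid always contains 0 and 1).
#' @param eco_window Ecological integration time per event (default 100 time
#'   units; doubling it is a standard robustness check).
#' @param intro_density Density at which a mutant is introduced
#'   (default `1e-4`).
#' @param extinct_threshold Phenotypes below this total density are culled
#'   (default `1e-5`).
#' @param ode_rtol,ode_atol Integration tolerances for the ecological
#'   windows.
#' @return An object of class `evosim_result` with the per-event trait
#'   distribution (see [tidy.evosim_result()]), the final phenotype table,
#'   the density-weighted final mean traits and an `extinct` flag.
#' @examples
#' \donttest{
#' host_params(beta0 = 8, f = 0.1, juvenile_target = "juvenile_mortality",
#'             adult_target = "reproduction") |>
#'   simulate_evolution(rJ_init = 0.5, rA_init = 0.5, n_events = 50,
#'                      seed = 1) |>
#'   glance()
#' }
#' @export
simulate_evolution <- function(params, rJ_init = 0.5, rA_init = 0.5,
                               n_events = 400, seed = NULL, step = 0.02,
                               eco_window = 100, intro_density = 1e-4,
                               extinct_threshold = 1e-5,
                               ode_rtol = 1e-7, ode_atol = 1e-9) {
  validate_params(params)
  if (n_events < 1) {
    abort("n_events must be at least 1", class = "ageresist_param_error")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- plist(params)
  snap <- function(r) min(max(round(r / step) * step, 0), 1)
  phen <- matrix(c(snap(rJ_init), snap(rA_init)), 1, 2,
                 dimnames = list(NULL, c("rJ", "rA")))
  dens <- matrix(0.1 / p$q, 1, 4,
                 dimnames = list(NULL, c("SJ", "SA", "IJ", "IA")))
  rates <- phen_rates(p, phen)
  summ <- vector("list", n_events)
  traj <- vector("list", n_events)
  extinct <- FALSE
  for (ev in seq_len(n_events)) {
    k <- nrow(phen)
    y0 <- as.numeric(dens)
    sol <- deSolve::lsoda(y0, c(0, eco_window),
                          function(t, y, parms) {
                            list(multi_rhs(pmax(y, 0), k, rates, p))
                          },
                          jacfunc = function(t, y, parms) {
                            multi_jac(pmax(y, 0), k, rates, p)
                          },
                          jactype = "fullusr",
                          parms = NULL, rtol = ode_rtol, atol = ode_atol)
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    dim(y) <- c(k, 4)
    dens <- y
    tot <- rowSums(dens)
    if (sum(tot) < 1e-8 / p$q) {
      extinct <- TRUE
      summ[[ev]] <- tibble(event = ev, mean_rJ = NA_real_,
                           mean_rA = NA_real_, var_rJ = NA_real_,
                           var_rA = NA_real_, n_phen = 0L, N = 0, I = 0)
      summ <- summ[seq_len(ev)]
      traj <- traj[seq_len(ev)]
      break
    }
    keep <- tot >= extinct_threshold / p$q
    if (!any(keep)) keep[which.max(tot)] <- TRUE
    phen <- phen[keep, , drop = FALSE]
    dens <- dens[keep, , drop = FALSE]
    rates <- phen_rates(p, phen)
    tot <- rowSums(dens)
    wmean <- function(v) sum(v * tot) / sum(tot)
    N <- sum(dens)
    It <- sum(dens[, 3:4])
    summ[[ev]] <- tibble(
      event = ev, mean_rJ = wmean(phen[, 1]), mean_rA = wmean(phen[, 2]),
      var_rJ = wmean(phen[, 1]^2) - wmean(phen[, 1])^2,
      var_rA = wmean(phen[, 2]^2) - wmean(phen[, 2])^2,
      n_phen = nrow(phen), N = N, I = It)
    traj[[ev]] <- tibble(event = ev, rJ = phen[, 1], rA = phen[, 2],
                         SJ = dens[, 1], SA = dens[, 2], IJ = dens[, 3],
                         IA = dens[, 4])
    # mutation: parent weighted by birth output, one trait, +/- one step
    if (intro_density <= 0) next
    birth <- pmax(rates$a * (1 - p$q * N) * (dens[, 2] + p$f * dens[, 4]), 0)
    if (sum(birth) <= 0) birth <- tot
    parent <- sample.int(nrow(phen), 1, prob = birth)
    trait <- if (runif(1) < 0.5) 1L else 2L
    dir <- if (runif(1) < 0.5) step else -step
    new_val <- phen[parent, trait] + dir
    if (new_val < -1e-12 || new_val > 1 + 1e-12) new_val <- phen[parent, trait] - dir
    new_val <- snap(new_val)
    mut <- phen[parent, ]
    mut[trait] <- new_val
    hit <- which(abs(phen[, 1] - mut[1]) < 1e-9 &
                   abs(phen[, 2] - mut[2]) < 1e-9)
    if (length(hit) > 0) {
      dens[hit[1], 1] <- dens[hit[1], 1] + intro_density / p$q
    } else {
      phen <- rbind(phen, mut)
      dens <- rbind(dens, c(intro_density / p$q, 0, 0, 0))
      rates <- phen_rates(p, phen)
    }
  }
  summary_tbl <- dplyr::bind_rows(summ)
  fin <- summary_tbl[nrow(summary_tbl), ]
  n_tail <- max(2, ceiling(nrow(summary_tbl) / 10))
  tail_means <- utils::tail(summary_tbl, n_tail)
  structure(
    list(summary = summary_tbl, trajectory = dplyr::bind_rows(traj),
         final_phenotypes = tibble(rJ = phen[, 1], rA = phen[, 2],
                                   SJ = dens[, 1], SA = dens[, 2],
                                   IJ = dens[, 3], IA = dens[, 4]),
         final_mean = c(rJ = fin$mean_rJ, rA = fin$mean_rA),
         drift = c(rJ = stats::sd(tail_means$mean_rJ),
                   rA = stats::sd(tail_means$mean_rA)),
         extinct = extinct, params = as_tibble(params)[1, ],
         seed = seed, step = step, n_events = nrow(summary_tbl)),
    class = "evosim_result")
}

#' @export
print.evosim_result <- function(x, ...) {
  cat("<evosim_result>", x$n_events, "events; final mean traits (rJ, rA) = (",
      signif(x$final_mean[[1]], 4), ",", signif(x$final_mean[[2]], 4), ")",
      if (x$extinct) "[host extinct]" else "", "\n")
  invisible(x)
}

#' Tidy / summarise an evolutionary simulation
#'
#' `tidy()` returns the per-event trait distribution summary (density-weighted
#' means and variances, phenotype counts, total and infected densities).
#' `glance()` returns a one-row summary with the final means, terminal
#' variances and a convergence diagnostic (`drift_*`: standard deviation of
#' the mean trait over the last 10% of events).
#'
#' @param x An `evosim_result`.
#' @param ... Unused.
#' @method tidy evosim_result
#' @export
tidy.evosim_result <- function(x, ...) x$summary

#' @rdname tidy.evosim_result
#' @method glance evosim_result
#' @export
glance.evosim_result <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  tibble(n_events = x$n_events,
         final_rJ = fin$mean_rJ, final_rA = fin$mean_rA,
         var_rJ = fin$var_rJ, var_rA = fin$var_rA,
         drift_rJ = x$drift[[1]], drift_rA = x$drift[[2]],
         extinct = x$extinct)
}

#' @rdname tidy.evosim_result
#' @param object An `evosim_result`.
#' @method autoplot evosim_result
#' @export
autoplot.evosim_result <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("mean_rJ", "mean_rA"), names_to = "trait",
                        values_to = "mean") |>
    dplyr::mutate(trait = ifelse(.data$trait == "mean_rJ", "juvenile",
                                 "adult"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$event, y = .data$mean,
                                  colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(juvenile = "red",
                                            adult = "blue")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "mutation event", y = "mean resistance",
                  colour = "trait")
}

#' Trait-distribution summary of a simulation
#'
#' Per-event mean, variance and modality of each trait's marginal density
#' distribution, plus a sustained-bimodality flag: the distribution of a
#' trait is called bimodal at an event when it has two modes separated by
#' more than 5 grid steps, and sustained when bimodality persists for more
#' than 20% of events in a row (a possible signature of evolutionary
#' branching).
#'
#' @param result An `evosim_result`.
#' @return A list with `series` (per-event tibble: means, variances,
#'   `modes_rJ`, `modes_rA`, `bimodal_rJ`, `bimodal_rA`) and
#'   `sustained_bimodality` (named logical for the two traits).
#' @export
trait_distribution_summary <- function(result) {
  if (!inherits(result, "evosim_result") || nrow(result$summary) == 0) {
    abort("expected a non-empty evosim_result",
          class = "ageresist_param_error")
  }
  step <- result$step
  count_modes <- function(traits, weights) {
    full <- seq(0, 1, by = step)
    wf <- rep(0, length(full))
    idx <- round(traits / step) + 1
    for (i in seq_along(idx)) wf[idx[i]] <- wf[idx[i]] + weights[i]
    pad <- c(0, wf, 0)
    is_max <- wf > 0.01 * max(wf) &
      wf >= pad[seq_along(wf)] & wf >= pad[seq_along(wf) + 2]
    # merge plateau runs of adjacent maxima into single modes
    r <- rle(is_max)
    modes <- integer(0)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (r$values[k]) modes <- c(modes, pos[k] + (r$lengths[k] - 1) %/% 2)
    }
    if (length(modes) < 2) return(list(n = length(modes), sep = 0))
    list(n = length(modes), sep = max(diff(range(modes))))
  }
  evs <- split(result$trajectory, result$trajectory$event)
  rows <- purrr::map(evs, function(d) {
    w <- d$SJ + d$SA + d$IJ + d$IA
    mJ <- count_modes(d$rJ, w)
    mA <- count_modes(d$rA, w)
    tibble(event = d$event[1],
           modes_rJ = mJ$n, modes_rA = mA$n,
           bimodal_rJ = mJ$n >= 2 && mJ$sep > 5,
           bimodal_rA = mA$n >= 2 && mA$sep > 5)
  })
  series <- dplyr::left_join(result$summary, dplyr::bind_rows(rows),
                             by = "event")
  longest_run <- function(flags) {
    r <- rle(flags)
    m <- r$lengths[r$values %in% TRUE]
    if (length(m) == 0) 0 else max(m)
  }
  n_ev <- nrow(series)
  list(series = series,
       sustained_bimodality = c(
         rJ = longest_run(series$bimodal_rJ) > 0.2 * n_ev,
         rA = longest_run(series$bimodal_rA) > 0.2 * n_ev))
}
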