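# Ecological (resident) dynamics: ODE right-hand side, analytic Jacobian,
# closed-form disease-free equilibrium and R0, numerical endemic equilibrium.
#
# Internal functions work on a parameter list `p` (one row of a host_params
# table) plus an effective-rate list `e`; exported wrappers are data-frame
# first and return tibbles.

state_names <- c("SJ", "SA", "IJ", "IA")

# dX/dt for state y = (SJ, SA, IJ, IA)
rhs_core <- function(y, p, e) {
  N <- y[1] + y[2] + y[3] + y[4]
  It <- y[3] + y[4]
  lJ <- e$betaJ * It
  lA <- e$betaA * It
  birth <- e$a * (1 - p$q * N) * (y[2] + p$f * y[4])
  c(birth - (e$bJ + e$g + lJ) * y[1],
    e$g * y[1] - (e$bA + lA) * y[2],
    lJ * y[1] - (e$bJ + e$g + p$alpha) * y[3],
    e$g * y[3] + lA * y[2] - (e$bA + p$alpha) * y[4])
}

# analytic Jacobian of rhs_core at y
jac_core <- function(y, p, e) {
  rep_pool <- y[2] + p$f * y[4]
  N <- sum(y)
  It <- y[3] + y[4]
  lJ <- e$betaJ * It
  lA <- e$betaA * It
  aq <- e$a * p$q * rep_pool
  a1 <- e$a * (1 - p$q * N)
  rbind(
    c(-aq - (e$bJ + e$g + lJ), a1 - aq, -aq - e$betaJ * y[1],
      a1 * p$f - aq - e$betaJ * y[1]),
    c(e$g, -(e$bA + lA), -e$betaA * y[2], -e$betaA * y[2]),
    c(lJ, 0, e$betaJ * y[1] - (e$bJ + e$g + p$alpha), e$betaJ * y[1]),
    c(0, lA, e$g + e$betaA * y[2], e$betaA * y[2] - (e$bA + p$alpha)))
}

# Host-only equilibrium. The viability surplus is ag - bA(bJ + g); note the
# outer denominators carry (bA + g): solving g SJ = bA SA together with the
# birth balance gives N* = surplus/(a g q) and SA* = g N*/(g + bA).
dfe_core <- function(p, e) {
  surplus <- e$a * e$g - e$bA * (e$bJ + e$g)
  if (surplus <= 0) return(NULL)
  c(SJ = e$bA * surplus / (e$a * e$g * (e$bA + e$g) * p$q),
    SA = surplus / (e$a * (e$bA + e$g) * p$q),
    IJ = 0, IA = 0)
}

# Next-generation R0 at the disease-free equilibrium:
# R0 = betaJ SJ* (bA+alpha+g)/((bJ+g+alpha)(bA+alpha)) + betaA SA*/(bA+alpha)
# which collapses to the closed form below (the (bA+g) factor comes from the
# disease-free equilibrium densities).
r0_closed <- function(p, e, rJ = p$rJ, rA = p$rA) {
  surplus <- e$a * e$g - e$bA * (e$bJ + e$g)
  if (surplus <= 0) return(NA_real_)
  p$beta0 * surplus *
    ((1 - rJ) * (e$bA + p$alpha + e$g) * e$bA +
       (1 - rA) * e$g * (e$bJ + p$alpha + e$g)) /
    (e$a * e$g * (e$bA + p$alpha) * (e$bA + e$g) * (e$bJ + e$g + p$alpha) *
       p$q)
}

max_re_eig <- function(J) max(Re(eigen(J, only.values = TRUE)$values))

# Damped Newton polish of an equilibrium candidate. Returns polished state or
# NULL if it fails to converge or leaves the admissible region.
newton_polish <- function(y, p, e, tol = 1e-13, max_iter = 40) {
  for (i in seq_len(max_iter)) {
    fv <- rhs_core(y, p, e)
    if (max(abs(fv)) < tol) return(y)
    J <- jac_core(y, p, e)
    step <- tryCatch(solve(J, fv), error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    f0 <- sum(fv^2)
    repeat {
      y_new <- y - lam * step
      f1 <- sum(rhs_core(y_new, p, e)^2)
      if (f1 < f0 || lam < 1 / 64) break
      lam <- lam / 2
    }
    y <- y_new
    if (any(y < -0.1) || any(!is.finite(y)) || sum(y) > 10 / p$q) return(NULL)
  }
  fv <- rhs_core(y, p, e)
  if (max(abs(fv)) < 1e-9) y else NULL
}

integrate_window <- function(y0, p, e, t_end, rtol = 1e-10, atol = 1e-12) {
  f_ode <- function(t, y, parms) list(rhs_core(y, p, e))
  j_ode <- function(t, y, parms) jac_core(y, p, e)
  out <- deSolve::lsoda(y0, c(0, t_end), f_ode, parms = NULL,
                        jacfunc = j_ode, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  pmax(as.numeric(out[nrow(out), 2:5]), 0)
}

# Full endemic-equilibrium solver for one parameter list.
# Returns list(state, kind, stable, residual, R0). `hint` is a nearby
# equilibrium state used for Newton continuation (verified stable and
# positive before acceptance; integration fallback otherwise).
solve_equilibrium <- function(p, rJ = p$rJ, rA = p$rA, y0 = NULL,
                              hint = NULL, t_chunk = 150, t_max = 6000) {
  e <- effective_rates_list(p, rJ, rA)
  dfe <- dfe_core(p, e)
  if (is.null(dfe)) {
    return(list(state = c(SJ = 0, SA = 0, IJ = 0, IA = 0), kind = "extinct",
                stable = TRUE, residual = 0, R0 = NA_real_))
  }
  R0 <- r0_closed(p, e, rJ, rA)
  as_df <- function() {
    J <- jac_core(dfe, p, e)
    list(state = dfe, kind = "disease_free", stable = max_re_eig(J) < 0,
         residual = max(abs(rhs_core(dfe, p, e))), R0 = R0)
  }
  if (R0 <= 1) return(as_df())
  if (!is.null(hint)) {
    pol <- newton_polish(hint, p, e)
    if (!is.null(pol) && all(pol > -1e-12)) {
      pol <- pmax(pol, 0)
      if (pol[3] + pol[4] > 1e-8 / p$q) {
        J <- jac_core(pol, p, e)
        if (max_re_eig(J) < 0) {
          return(list(state = setNames(pol, state_names), kind = "endemic",
                      stable = TRUE,
                      residual = max(abs(rhs_core(pol, p, e))), R0 = R0))
        }
      }
    }
  }
  y <- y0 %||% rep(0.1 / p$q, 4)
  t_done <- 0
  while (t_done < t_max) {
    y <- integrate_window(y, p, e, t_chunk)
    t_done <- t_done + t_chunk
    if (sum(y) < 1e-8 / p$q) {
      return(list(state = setNames(pmax(y, 0), state_names), kind = "extinct",
                  stable = NA, residual = max(abs(rhs_core(y, p, e))),
                  R0 = R0))
    }
    pol <- newton_polish(y, p, e)
    if (!is.null(pol) && all(pol > -1e-12)) {
      pol <- pmax(pol, 0)
      if (pol[3] + pol[4] > 1e-8 / p$q) {
        J <- jac_core(pol, p, e)
        return(list(state = setNames(pol, state_names), kind = "endemic",
                    stable = max_re_eig(J) < 0,
                    residual = max(abs(rhs_core(pol, p, e))), R0 = R0))
      }
      # converged to the disease-free state despite R0 > 1: keep integrating
      # unless we are out of budget
      if (t_done >= t_max) break
    }
  }
  abort(paste0("endemic equilibrium solver failed to converge (R0 = ",
               signif(R0, 6), ")"),
        class = "ageresist_solver_failure")
}

equilibrium_row <- function(eq) {
  tibble(SJ = eq$state[[1]], SA = eq$state[[2]], IJ = eq$state[[3]],
         IA = eq$state[[4]], N = sum(eq$state), I = eq$state[[3]] + eq$state[[4]],
         kind = eq$kind, stable = eq$stable, residual = eq$residual,
         R0 = eq$R0)
}

#' Right-hand side of the ecological ODE system
#'
#' Time derivatives of the susceptible/infected juvenile/adult densities
#' under the age-structured SI model: density-dependent reproduction into the
#' susceptible juvenile class (infected adults reproduce at a fraction `f`),
#' maturation `g`, natural mortality `bJ`/`bA`, mortality virulence `alpha`
#' and density-dependent transmission with force of infection
#' `beta_i * (IJ + IA)`.
#'
#' @param state Data frame (or coercible) with columns `SJ`, `SA`, `IJ`, `IA`
#'   (non-negative densities); one row per evaluation.
#' @param params A one-row `host_params` tibble.
#' @return A tibble with columns `dSJ`, `dSA`, `dIJ`, `dIA`.
#' @examples
#' ode_rhs(data.frame(SJ = 0.3, SA = 0.3, IJ = 0, IA = 0), host_params())
#' @export
ode_rhs <- function(state, params) {
  validate_params(params)
  state <- as.data.frame(state)
  if (!all(state_names %in% names(state))) {
    abort("state must have columns SJ, SA, IJ, IA",
          class = "ageresist_param_error")
  }
  if (any(as.matrix(state[, state_names]) < 0)) {
    abort("densities must be non-negative", class = "ageresist_param_error")
  }
  p <- plist(params)
  e <- effective_rates_list(p)
  out <- t(apply(as.matrix(state[, state_names]), 1,
                 function(y) rhs_core(y, p, e)))
  tibble(dSJ = unname(out[, 1]), dSA = unname(out[, 2]),
         dIJ = unname(out[, 3]), dIA = unname(out[, 4]))
}

#' Integrate the ecological dynamics
#'
#' Solves the SI ODE system forward in time with a stiff solver (`lsoda`,
#' analytic Jacobian supplied) and returns the trajectory in long-friendly
#' wide format.
#'
#' @param params A one-row `host_params` tibble.
#' @param state0 Named numeric vector or one-row data frame with `SJ`, `SA`,
#'   `IJ`, `IA`; defaults to 0.1 in every class.
#' @param times Numeric vector of output times.
#' @return A tibble with columns `time`, `SJ`, `SA`, `IJ`, `IA`, `N`, `I`.
#' @export
ecology_dynamics <- function(params, state0 = NULL,
                             times = seq(0, 100, by = 1)) {
  validate_params(params)
  p <- plist(params)
  e <- effective_rates_list(p)
  y0 <- if (is.null(state0)) {
    setNames(rep(0.1 / p$q, 4), state_names)
  } else {
    y <- unlist(as.data.frame(state0)[1, state_names])
    setNames(as.numeric(y), state_names)
  }
  f_ode <- function(t, y, parms) list(rhs_core(y, p, e))
  j_ode <- function(t, y, parms) jac_core(y, p, e)
  out <- deSolve::lsoda(y0, times, f_ode, parms = NULL, jacfunc = j_ode,
                        jactype = "fullusr", rtol = 1e-9, atol = 1e-11)
  out <- as.data.frame(out)
  names(out) <- c("time", state_names)
  out |>
    as_tibble() |>
    dplyr::mutate(N = .data$SJ + .data$SA + .data$IJ + .data$IA,
                  I = .data$IJ + .data$IA)
}

#' Disease-free equilibrium (closed form)
#'
#' The equilibrium of the host population in the absence of infection:
#' `SJ* = bA (ag - bA(bJ + g)) / (a g (bA + g) q)` and
#' `SA* = (ag - bA(bJ + g)) / (a (bA + g) q)` at the effective
#' (trade-off-modified) rates. When `ag <= bA (bJ + g)` hosts are removed
#' faster than they are produced and the population is not viable
#' (`kind = "extinct"`).
#'
#' @param params A `host_params` tibble (any number of rows).
#' @return The input with equilibrium columns `SJ`, `SA`, `IJ`, `IA`, `N`,
#'   `I`, `kind`, `stable`, `residual`, `R0` appended. `stable` refers to the
#'   full system, so a viable host with `R0 > 1` has an unstable disease-free
#'   equilibrium.
#' @examples
#' host_params(beta0 = 0.5) |> disease_free_equilibrium()
#' @export
disease_free_equilibrium <- function(params) {
  validate_params(params)
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    p <- plist(params, i)
    e <- effective_rates_list(p)
    dfe <- dfe_core(p, e)
    if (is.null(dfe)) {
      return(tibble(SJ = 0, SA = 0, IJ = 0, IA = 0, N = 0, I = 0,
                    kind = "extinct", stable = TRUE, residual = 0,
                    R0 = NA_real_))
    }
    J <- jac_core(dfe, p, e)
    tibble(SJ = dfe[[1]], SA = dfe[[2]], IJ = 0, IA = 0,
           N = dfe[[1]] + dfe[[2]], I = 0, kind = "disease_free",
           stable = max_re_eig(J) < 0,
           residual = max(abs(rhs_core(dfe, p, e))),
           R0 = r0_closed(p, e))
  })
  dplyr::bind_cols(as_tibble(params), dplyr::bind_rows(rows))
}

#' Basic reproduction number of the pathogen
#'
#' Closed-form `R0` at the disease-free equilibrium, derived by the
#' next-generation method for the two infected classes:
#' \deqn{R_0 = \frac{\beta_0 (ag - b_A(b_J+g)) [(1-r_J)(b_A+\alpha+g) b_A +
#'   (1-r_A) g (b_J+\alpha+g)]}{a g (b_A+\alpha)(b_A+g)(b_J+g+\alpha) q}.}
#' The disease can invade the host population if and only if `R0 > 1`.
#'
#' @param params A `host_params` tibble (any number of rows).
#' @return The input with an `R0` column appended (`NA` when the host is not
#'   viable).
#' @examples
#' host_params(beta0 = 8) |> r0()
#' @export
r0 <- function(params) {
  validate_params(params)
  vals <- purrr::map_dbl(seq_len(nrow(params)), function(i) {
    p <- plist(params, i)
    r0_closed(p, effective_rates_list(p))
  })
  dplyr::bind_cols(as_tibble(params), tibble(R0 = vals))
}

#' Endemic equilibrium of the ecological dynamics
#'
#' Finds the stable endemic equilibrium numerically (there is no analytic
#' expression): the system is integrated from an interior initial condition
#' with a stiff solver, then the state is polished to machine precision with a
#' damped Newton iteration on the analytic Jacobian. When `R0 <= 1` the
#' disease cannot persist and the disease-free equilibrium is returned; when
#' the host is not viable `kind = "extinct"`. A solver failure raises a
#' classed error (`ageresist_solver_failure`), never a silent wrong state.
#'
#' @param params A `host_params` tibble (any number of rows).
#' @param multistart If `TRUE`, solve from 5 spread-out initial conditions and
#'   report the number of distinct equilibria found (guard against ecological
#'   bistability; the analysed parameter regions have a single stable endemic
#'   equilibrium).
#' @param initial_state Optional numeric vector `(SJ, SA, IJ, IA)` used as
#'   the starting point of the integration (an initial guess for the
#'   equilibrium); defaults to 0.1 in every class.
#' @return The input with equilibrium columns appended (as in
#'   [disease_free_equilibrium()]); with `multistart = TRUE` also
#'   `n_equilibria`.
#' @examples
#' host_params(beta0 = 8, f = 0.1) |> endemic_equilibrium()
#' @export
endemic_equilibrium <- function(params, multistart = FALSE,
                                initial_state = NULL) {
  validate_params(params)
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    p <- plist(params, i)
    if (!multistart) {
      return(equilibrium_row(solve_equilibrium(p, y0 = initial_state)))
    }
    starts <- list(rep(0.1, 4), rep(0.5, 4), c(0.02, 0.02, 0.4, 0.4),
                   c(0.4, 0.4, 0.02, 0.02), rep(0.01, 4))
    eqs <- purrr::map(starts, function(s) {
      solve_equilibrium(p, y0 = s / p$q)
    })
    states <- do.call(rbind, purrr::map(eqs, "state"))
    dis <- !duplicated(round(states, 6))
    out <- equilibrium_row(eqs[[1]])
    out$n_equilibria <- sum(dis)
    out
  })
  dplyr::bind_cols(as_tibble(params), dplyr::bind_rows(rows))
}

#' Critical transmissibility for disease persistence
#'
#' Bisects on the baseline transmission rate `beta0` for the smallest value at
#' which a positive endemic equilibrium exists, using continuation: the
#' endemic state found at the upper bracket seeds the Newton solve at each
#' midpoint, so detection stays sharp arbitrarily close to the threshold. At
#' the epidemic threshold the closed-form `R0` equals 1.
#'
#' @param params A one-row `host_params` tibble; its `beta0` is ignored.
#' @param lower,upper Bracket for `beta0` (endemic equilibrium must exist at
#'   `upper` and not at `lower`).
#' @param tol Bisection tolerance on `beta0`. Default `1e-6`.
#' @return A one-row tibble with `beta0_crit` and `R0_at_crit` (closed-form
#'   `R0` evaluated at the critical `beta0`).
#' @export
critical_beta0 <- function(params, lower = 1e-3, upper = 5, tol = 1e-6) {
  validate_params(params)
  p <- plist(params)
  endemic_state <- function(beta0, y0) {
    p2 <- p
    p2$beta0 <- beta0
    e <- effective_rates_list(p2)
    R0 <- r0_closed(p2, e)
    if (is.na(R0)) return(NULL)
    y <- if (!is.null(y0)) newton_polish(y0, p2, e) else NULL
    if (is.null(y)) {
      eq <- tryCatch(solve_equilibrium(p2), error = function(err) NULL)
      if (is.null(eq) || eq$kind != "endemic") return(NULL)
      y <- eq$state
    }
    y <- pmax(y, 0)
    if (y[3] + y[4] > 1e-9 / p2$q && all(y >= 0)) y else NULL
  }
  y_hi <- endemic_state(upper, NULL)
  if (is.null(y_hi)) {
    abort("no endemic equilibrium at the upper bracket",
          class = "ageresist_solver_failure")
  }
  if (!is.null(endemic_state(lower, y_hi))) {
    abort("endemic equilibrium already exists at the lower bracket",
          class = "ageresist_solver_failure")
  }
  lo <- lower
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    y_mid <- endemic_state(mid, y_hi)
    if (is.null(y_mid)) {
      lo <- mid
    } else {
      hi <- mid
      y_hi <- y_mid
    }
  }
  beta_crit <- (lo + hi) / 2
  p2 <- p
  p2$beta0 <- beta_crit
  tibble(beta0_crit = beta_crit,
         R0_at_crit = r0_closed(p2, effective_rates_list(p2)))
}
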