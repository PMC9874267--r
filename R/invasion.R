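# Evolutionary invasion analysis (adaptive dynamics): mutant invasion
# fitness, selection gradients, co-singular strategies and their stability.
#
# The mutant fitness expressions are closed-form in the resident endemic
# equilibrium, so a resident_context (one equilibrium solve) makes all mutant
# evaluations cheap; only changes to the *resident* traits require a new
# equilibrium solve.

grad_step <- 1e-5   # finite-difference step for selection gradients
hess_step <- 1e-4   # step for second derivatives / gradient Jacobians

#' Resident context for invasion analysis
#'
#' Solves the resident endemic equilibrium and packages the quantities that a
#' rare mutant experiences: total density `N*`, infected density `I*` and the
#' stage-specific forces of infection `lambdaJ* = betaJ (IJ* + IA*)`,
#' `lambdaA*`. Invasion fitness is defined against an endemic resident, so a
#' disease-free or extinct resident is an error.
#'
#' @param params A one-row `host_params` tibble (the resident traits are its
#'   `rJ`, `rA` columns).
#' @return An object of class `resident_context`.
#' @export
resident_context <- function(params) {
  validate_params(params)
  p <- plist(params)
  eq <- solve_equilibrium(p)
  if (eq$kind != "endemic") {
    abort(paste0("invasion fitness requires an endemic resident (got ",
                 eq$kind, ")"),
          class = "ageresist_domain_error")
  }
  e <- effective_rates_list(p)
  It <- eq$state[[3]] + eq$state[[4]]
  structure(
    list(p = p, e = e, state = eq$state, N = sum(eq$state), I = It,
         lambdaJ = e$betaJ * It, lambdaA = e$betaA * It,
         R0 = eq$R0, residual = eq$residual, params = as_tibble(params)),
    class = "resident_context")
}

#' @export
print.resident_context <- function(x, ...) {
  cat("<resident_context> rJ =", x$p$rJ, " rA =", x$p$rA,
      " N* =", signif(x$N, 6), " I* =", signif(x$I, 6),
      " R0 =", signif(x$R0, 6), "\n")
  invisible(x)
}

#' @method tidy resident_context
#' @export
tidy.resident_context <- function(x, ...) {
  tibble(SJ = x$state[[1]], SA = x$state[[2]], IJ = x$state[[3]],
         IA = x$state[[4]], N = x$N, I = x$I,
         lambdaJ = x$lambdaJ, lambdaA = x$lambdaA)
}

#' @method glance resident_context
#' @export
glance.resident_context <- function(x, ...) {
  tibble(rJ = x$p$rJ, rA = x$p$rA, R0 = x$R0, N = x$N, I = x$I,
         residual = x$residual)
}

# closed-form invasion fitness of a mutant differing from the resident in a
# single stage trait, with the resident environment (N*, lambda*) frozen
wfit_core <- function(ctx, stage, rm) {
  p <- ctx$p
  er <- ctx$e
  alpha <- p$alpha
  f <- p$f
  fac <- 1 - p$q * ctx$N
  if (stage == "juvenile") {
    em <- effective_rates_list(p, rJ = rm, rA = p$rA)
    lJ <- p$beta0 * (1 - rm) * ctx$I
    lA <- ctx$lambdaA
    A <- (er$bA + alpha) * (em$bJ + em$g + alpha) +
      f * (em$bJ + em$g + alpha) * lA + f * lJ * (er$bA + lA)
    em$g * em$a * fac * A /
      ((er$bA + alpha) * (em$bJ + em$g + alpha) * (er$bA + lA) *
         (em$bJ + em$g + lJ)) - 1
  } else {
    em <- effective_rates_list(p, rJ = p$rJ, rA = rm)
    lA <- p$beta0 * (1 - rm) * ctx$I
    lJ <- ctx$lambdaJ
    A <- (em$bA + alpha) * (er$bJ + er$g + alpha) +
      f * (er$bJ + er$g + alpha) * lA + f * lJ * (em$bA + lA)
    er$g * em$a * fac * A /
      ((em$bA + alpha) * (er$bJ + er$g + alpha) * (em$bA + lA) *
         (er$bJ + er$g + lJ)) - 1
  }
}

as_context <- function(x) {
  if (inherits(x, "resident_context")) return(x)
  if (is.data.frame(x)) return(resident_context(x))
  abort("expected a host_params data frame or a resident_context",
        class = "ageresist_param_error")
}

#' Invasion fitness of a rare mutant
#'
#' Sign-meaningful fitness of a rare mutant differing from the resident in
#' one stage's resistance trait, evaluated against the resident's endemic
#' equilibrium (densities and forces of infection frozen at their resident
#' values). The mutant can invade if and only if the fitness is positive;
#' a mutant identical to the resident has fitness 0.
#'
#' @param x A one-row `host_params` tibble or a [resident_context()].
#' @param stage `"juvenile"` or `"adult"`: which trait the mutant carries.
#' @param r_m Mutant resistance value(s) in `[0, 1]` (vectorised).
#' @return A tibble with columns `stage`, `r_m`, `fitness`.
#' @examples
#' host_params(beta0 = 8, f = 0.1,
#'             juvenile_target = "juvenile_mortality") |>
#'   invasion_fitness("juvenile", c(0, 0.05, 0.1))
#' @export
invasion_fitness <- function(x, stage = c("juvenile", "adult"), r_m) {
  stage <- match.arg(stage)
  ctx <- as_context(x)
  if (any(r_m < 0 | r_m > 1)) {
    abort("mutant trait must lie in [0, 1]", class = "ageresist_param_error")
  }
  fit <- purrr::map_dbl(r_m, function(r) wfit_core(ctx, stage, r))
  tibble(stage = stage, r_m = r_m, fitness = fit)
}

# gradient of w_i with respect to its own mutant trait at mutant = resident;
# central differences, one-sided at the trait boundaries
grad_core <- function(ctx, h = grad_step) {
  g1 <- function(stage, r) {
    if (r < h) {
      (wfit_core(ctx, stage, r + h) - wfit_core(ctx, stage, r)) / h
    } else if (r > 1 - h) {
      (wfit_core(ctx, stage, r) - wfit_core(ctx, stage, r - h)) / h
    } else {
      (wfit_core(ctx, stage, r + h) - wfit_core(ctx, stage, r - h)) / (2 * h)
    }
  }
  c(dwJ = g1("juvenile", ctx$p$rJ), dwA = g1("adult", ctx$p$rA))
}

#' Selection gradients on juvenile and adult resistance
#'
#' Fitness gradients of the two resistance traits at mutant = resident:
#' the derivative of each stage's invasion fitness with respect to its own
#' mutant trait, by central finite differences (step `1e-5`, one-sided at the
#' trait boundaries). A positive component means selection for higher
#' resistance at that stage. Rows whose resident is not endemic get `NA`
#' gradients and the equilibrium `kind` is reported.
#'
#' @param params A `host_params` tibble (any number of rows), or a
#'   [resident_context()].
#' @return The parameter rows with columns `dwJ`, `dwA` and `kind` appended.
#' @export
selection_gradients <- function(params) {
  if (inherits(params, "resident_context")) {
    g <- grad_core(params)
    return(dplyr::bind_cols(params$params,
                            tibble(dwJ = g[[1]], dwA = g[[2]],
                                   kind = "endemic")))
  }
  validate_params(params)
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    ctx <- tryCatch(resident_context(params[i, ]),
                    ageresist_domain_error = function(err) NULL)
    if (is.null(ctx)) {
      p <- plist(params, i)
      eq <- solve_equilibrium(p)
      return(tibble(dwJ = NA_real_, dwA = NA_real_, kind = eq$kind))
    }
    g <- grad_core(ctx)
    tibble(dwJ = g[[1]], dwA = g[[2]], kind = "endemic")
  })
  dplyr::bind_cols(as_tibble(params), dplyr::bind_rows(rows))
}

# Gradients at arbitrary resident traits, with the resident equilibrium kind.
# `cache` is an environment whose $state field carries a continuation hint
# between nearby calls. With allow_df = TRUE, a viable disease-free resident
# yields the cost-only selection gradients (mutant invasion into the
# disease-free equilibrium); otherwise non-endemic residents give NA.
grad_kind_at <- function(p, rJ, rA, cache = NULL, allow_df = FALSE) {
  p2 <- p
  p2$rJ <- min(max(rJ, 0), 1)
  p2$rA <- min(max(rA, 0), 1)
  hint <- if (!is.null(cache)) cache$state else NULL
  eq <- tryCatch(solve_equilibrium(p2, hint = hint),
                 error = function(err) NULL)
  if (is.null(eq)) {
    return(list(g = c(dwJ = NA_real_, dwA = NA_real_), kind = "failed"))
  }
  if (eq$kind == "endemic" && !is.null(cache)) cache$state <- eq$state
  if (eq$kind != "endemic" && !(allow_df && eq$kind == "disease_free")) {
    return(list(g = c(dwJ = NA_real_, dwA = NA_real_), kind = eq$kind))
  }
  e <- effective_rates_list(p2)
  It <- eq$state[[3]] + eq$state[[4]]
  ctx <- structure(
    list(p = p2, e = e, state = eq$state, N = sum(eq$state), I = It,
         lambdaJ = e$betaJ * It, lambdaA = e$betaA * It, R0 = eq$R0),
    class = "resident_context")
  list(g = grad_core(ctx), kind = eq$kind)
}

grad_at <- function(p, rJ, rA, cache = NULL, allow_df = FALSE) {
  grad_kind_at(p, rJ, rA, cache, allow_df)$g
}

#' Evolutionary stability at a co-singular strategy
#'
#' Second derivative of each stage's invasion fitness with respect to its own
#' mutant trait (finite differences, step `1e-4`), evaluated at the given
#' resident traits. A trait is evolutionarily stable (uninvadable) when the
#' second derivative is negative; magnitudes below `1e-6` are flagged
#' indeterminate.
#'
#' @param params A one-row `host_params` tibble.
#' @param rJ,rA The co-singular strategy (defaults to the resident traits in
#'   `params`).
#' @param h Finite-difference step for the second derivatives (default
#'   `1e-4`).
#' @return One-row tibble: `d2wJ`, `d2wA`, `es_J`, `es_A`, `es_indeterminate`.
#' @export
evolutionary_stability <- function(params, rJ = NULL, rA = NULL,
                                   h = hess_step) {
  validate_params(params)
  p <- plist(params)
  p$rJ <- rJ %||% p$rJ
  p$rA <- rA %||% p$rA
  ctx <- resident_context(dplyr::mutate(as_tibble(params),
                                        rJ = p$rJ, rA = p$rA))
  d2 <- function(stage, r) {
    r0_ <- min(max(r, h), 1 - h)
    (wfit_core(ctx, stage, r0_ + h) - 2 * wfit_core(ctx, stage, r0_) +
        wfit_core(ctx, stage, r0_ - h)) / h^2
  }
  d2J <- d2("juvenile", p$rJ)
  d2A <- d2("adult", p$rA)
  tibble(d2wJ = d2J, d2wA = d2A, es_J = d2J < 0, es_A = d2A < 0,
         es_indeterminate = abs(d2J) < 1e-6 | abs(d2A) < 1e-6)
}

# Jacobian of the selection-gradient field with respect to the resident
# traits (forward differences, step hess_step)
grad_jacobian <- function(p, rJ, rA, h = hess_step, cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  g0 <- grad_at(p, rJ, rA, cache)
  hj <- if (rJ + h <= 1) h else -h
  ha <- if (rA + h <= 1) h else -h
  gJ <- grad_at(p, rJ + hj, rA, cache)
  gA <- grad_at(p, rJ, rA + ha, cache)
  J <- cbind((gJ - g0) / hj, (gA - g0) / ha)
  dimnames(J) <- list(c("dwJ", "dwA"), c("rJ", "rA"))
  J
}

#' Strong convergence stability at a co-singular strategy
#'
#' Builds the Jacobian `J` of the selection-gradient vector with respect to
#' the resident traits (finite differences) and tests strong convergence
#' stability via negative definiteness of the symmetric part `J + t(J)` — a
#' sufficient condition for the singular strategy to attract gradual
#' evolution under any symmetric mutational covariance (and hence for the
#' eigenvalues of `J` to have negative real parts under equal mutation
#' rates). Near-singular Jacobians are flagged indeterminate.
#'
#' @inheritParams evolutionary_stability
#' @return One-row tibble: `strongly_convergent`, raw Jacobian eigenvalue
#'   real parts `eig1`, `eig2`, and `conv_indeterminate`.
#' @export
convergence_stability <- function(params, rJ = NULL, rA = NULL,
                                  h = hess_step) {
  validate_params(params)
  p <- plist(params)
  J <- grad_jacobian(p, rJ %||% p$rJ, rA %||% p$rA, h = h)
  if (any(!is.finite(J))) {
    return(tibble(strongly_convergent = NA, eig1 = NA_real_,
                  eig2 = NA_real_, conv_indeterminate = TRUE))
  }
  sym_eig <- eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values
  raw <- sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
  tibble(strongly_convergent = all(sym_eig < 0),
         eig1 = raw[1], eig2 = raw[2],
         conv_indeterminate = max(abs(sym_eig)) < 1e-6 ||
           abs(det(J)) < 1e-10)
}

classify_point <- function(es_J, es_A, strongly_convergent, sym_eig_max) {
  if (isTRUE(strongly_convergent)) {
    if (isTRUE(es_J) && isTRUE(es_A)) "CSS" else "branching-candidate"
  } else if (!is.na(sym_eig_max) && sym_eig_max > 0 &&
             isTRUE(strongly_convergent == FALSE)) {
    "saddle-like"
  } else {
    "repeller"
  }
}

# classify interior singular point; returns one-row tibble
classify_interior <- function(params1, p, rJ, rA, gres) {
  es <- evolutionary_stability(params1, rJ, rA)
  J <- grad_jacobian(p, rJ, rA)
  if (any(!is.finite(J))) {
    return(tibble(rJ_star = rJ, rA_star = rA, boundary = "none",
                  es_J = NA, es_A = NA, strongly_convergent = NA,
                  classification = "indeterminate", attractor = NA,
                  grad_resid = gres))
  }
  sym_eig <- eigen((J + t(J)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values
  conv <- all(sym_eig < 0)
  cls <- if (conv) {
    if (es$es_J && es$es_A) "CSS" else "branching-candidate"
  } else if (all(sym_eig > 0)) {
    "repeller"
  } else {
    "saddle-like"
  }
  tibble(rJ_star = rJ, rA_star = rA, boundary = "none",
         es_J = es$es_J, es_A = es$es_A, strongly_convergent = conv,
         classification = cls, attractor = conv, grad_resid = gres)
}

# damped Newton on the 2-D gradient field, staying in the open square
newton_2d <- function(p, start, tol = 1e-8, max_iter = 30) {
  cache <- new.env(parent = emptyenv())
  x <- pmin(pmax(start, 1e-4), 1 - 1e-4)
  for (i in seq_len(max_iter)) {
    g <- grad_at(p, x[1], x[2], cache)
    if (any(!is.finite(g))) return(NULL)
    if (max(abs(g)) < tol) return(list(x = x, resid = max(abs(g))))
    J <- grad_jacobian(p, x[1], x[2], cache = cache)
    if (any(!is.finite(J)) || abs(det(J)) < 1e-14) return(NULL)
    step <- solve(J, g)
    lam <- 1
    repeat {
      x_new <- x - lam * step
      if (all(x_new > 1e-4) && all(x_new < 1 - 1e-4)) {
        g_new <- grad_at(p, x_new[1], x_new[2], cache)
        if (all(is.finite(g_new)) && max(abs(g_new)) < max(abs(g)) * 0.9) break
      }
      lam <- lam / 2
      if (lam < 1 / 256) {
        x_new <- pmin(pmax(x - lam * 2 * step, 1e-4), 1 - 1e-4)
        break
      }
    }
    if (max(abs(x_new - x)) < 1e-12) return(NULL)
    x <- x_new
  }
  g <- grad_at(p, x[1], x[2], cache)
  if (all(is.finite(g)) && max(abs(g)) < 1e-7) {
    list(x = x, resid = max(abs(g)))
  } else {
    NULL
  }
}

# evaluate gradients on an n x n lattice over [0,1]^2; each rA-column is
# walked with its own continuation cache so neighbouring solves seed Newton
gradient_grid <- function(p, n, allow_df = FALSE) {
  rs <- seq(0, 1, length.out = n)
  grid <- expand.grid(rJ = rs, rA = rs)
  g <- matrix(NA_real_, nrow(grid), 2)
  kind <- character(nrow(grid))
  for (j in seq_len(n)) {
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      k <- (j - 1) * n + i
      res <- grad_kind_at(p, grid$rJ[k], grid$rA[k], cache, allow_df)
      g[k, ] <- res$g
      kind[k] <- res$kind
    }
  }
  tibble(rJ = grid$rJ, rA = grid$rA, dwJ = g[, 1], dwA = g[, 2],
         kind = kind)
}

#' Find co-singular resistance strategies
#'
#' Locates pairs of trait values at which both selection gradients vanish
#' (interior co-singular strategies) as well as boundary and corner singular
#' strategies where a pinned trait's gradient pushes against the edge of the
#' unit square. Interior roots are found by damped Newton iteration on the
#' gradient field, seeded from user starts plus cells of a sign-change grid;
#' duplicates within `1e-5` are merged (keeping the smaller gradient
#' residual). Each point is classified by evolutionary stability (second
#' derivatives) and strong convergence stability (symmetric part of the
#' gradient Jacobian): a `CSS` is both; a convergence-stable point that is
#' invadable is a `branching-candidate`; non-convergent points are
#' `repeller`/`saddle-like`. Boundary points are flagged in the `boundary`
#' column and classified `boundary-attractor`/`boundary-repeller`.
#'
#' If no singular strategy is found, the returned (empty) tibble carries the
#' gradient sign grid as attribute `"sign_grid"` for diagnosis.
#'
#' @param params A one-row `host_params` tibble.
#' @param starts Optional matrix or data frame of additional (rJ, rA) starts.
#' @param grid_n Resolution of the sign-scan lattice used to seed root
#'   searches (default 6).
#' @return A tibble with one row per singular strategy: `rJ_star`, `rA_star`,
#'   `boundary`, `es_J`, `es_A`, `strongly_convergent`, `classification`,
#'   `attractor`, `grad_resid`, plus resident equilibrium summaries
#'   `N_star`, `I_star`, `R0`.
#' @examples
#' \donttest{
#' host_params(beta0 = 8, f = 0.1, juvenile_target = "juvenile_mortality",
#'             adult_target = "reproduction") |> find_cosingular()
#' }
#' @export
find_cosingular <- function(params, starts = NULL, grid_n = 6) {
  validate_params(params)
  p <- plist(params)
  params1 <- as_tibble(params)[1, ]
  grid <- gradient_grid(p, grid_n)
  find_cosingular_core(params1, p, grid, starts, grid_n)
}

find_cosingular_core <- function(params1, p, grid, starts = NULL,
                                 grid_n = 6) {
  rs <- sort(unique(grid$rJ))
  n <- length(rs)
  mJ <- matrix(grid$dwJ, n, n)   # rows: rJ index, cols: rA index
  mA <- matrix(grid$dwA, n, n)
  results <- list()

  # --- interior roots: seed from cells where both components change sign
  seeds <- list()
  if (!is.null(starts)) {
    starts <- as.matrix(as.data.frame(starts))
    seeds <- c(seeds, lapply(seq_len(nrow(starts)),
                             function(i) as.numeric(starts[i, 1:2])))
  }
  sgn <- function(x) ifelse(is.na(x), NA, sign(x))
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n - 1)) {
      cj <- c(mJ[i, j], mJ[i + 1, j], mJ[i, j + 1], mJ[i + 1, j + 1])
      ca <- c(mA[i, j], mA[i + 1, j], mA[i, j + 1], mA[i + 1, j + 1])
      if (any(is.na(cj)) || any(is.na(ca))) next
      if (length(unique(sgn(cj))) > 1 && length(unique(sgn(ca))) > 1) {
        seeds <- c(seeds, list(c(mean(rs[i:(i + 1)]), mean(rs[j:(j + 1)]))))
      }
    }
  }
  for (s in seeds) {
    root <- newton_2d(p, s)
    if (is.null(root)) next
    x <- root$x
    if (min(x) < 5e-4 || max(x) > 1 - 5e-4) next  # boundary handled below
    results <- c(results, list(
      classify_interior(params1, p, x[1], x[2], root$resid)))
  }

  # --- edge singular strategies: free-trait gradient root with the pinned
  # trait's gradient pushing outward
  edge_specs <- list(
    list(pin = "rJ", val = 0, out = function(g) g[1] < 0),
    list(pin = "rJ", val = 1, out = function(g) g[1] > 0),
    list(pin = "rA", val = 0, out = function(g) g[2] < 0),
    list(pin = "rA", val = 1, out = function(g) g[2] > 0))
  for (spec in edge_specs) {
    cache <- new.env(parent = emptyenv())
    free_grad <- function(x) {
      g <- if (spec$pin == "rJ") grad_at(p, spec$val, x, cache) else
        grad_at(p, x, spec$val, cache)
      if (spec$pin == "rJ") c(free = g[[2]], g) else c(free = g[[1]], g)
    }
    vals <- if (spec$pin == "rJ") mA[which(rs == spec$val), ] else
      mJ[, which(rs == spec$val)]
    for (k in seq_len(n - 1)) {
      v1 <- vals[k]
      v2 <- vals[k + 1]
      if (is.na(v1) || is.na(v2) || sign(v1) == sign(v2)) next
      root <- tryCatch(
        uniroot(function(x) free_grad(x)[["free"]],
                c(rs[k], rs[k + 1]), tol = 1e-9),
        error = function(err) NULL)
      if (is.null(root)) next
      g <- free_grad(root$root)
      if (any(!is.finite(g))) next
      if (!spec$out(c(g[["dwJ"]], g[["dwA"]]))) next
      pt <- if (spec$pin == "rJ") c(spec$val, root$root) else
        c(root$root, spec$val)
      results <- c(results, list(
        classify_boundary(params1, p, pt[1], pt[2], spec,
                          gres = abs(g[["free"]]))))
    }
    # eradication-frontier attractor on this edge: R0 crosses 1 along the
    # edge and the endemic-side flow pushes resistance against the frontier
    fr <- frontier_on_edge(p, spec)
    if (!is.null(fr)) results <- c(results, list(fr))
  }

  # --- corner singular strategies: both gradients pushing outward
  # (cost-only gradients at a viable disease-free corner count: selection
  # against costly resistance still pins the traits there)
  for (cj in c(0, 1)) {
    for (ca in c(0, 1)) {
      g <- grad_at(p, cj, ca, allow_df = TRUE)
      if (any(!is.finite(g))) next
      outJ <- if (cj == 0) g[[1]] < 0 else g[[1]] > 0
      outA <- if (ca == 0) g[[2]] < 0 else g[[2]] > 0
      if (outJ && outA) {
        results <- c(results, list(
          tibble(rJ_star = cj, rA_star = ca,
                 boundary = paste0("corner(", cj, ",", ca, ")"),
                 es_J = NA, es_A = NA, strongly_convergent = NA,
                 classification = "boundary-attractor", attractor = TRUE,
                 grad_resid = 0)))
      }
    }
  }

  out <- if (length(results) == 0) {
    tibble(rJ_star = numeric(), rA_star = numeric(), boundary = character(),
           es_J = logical(), es_A = logical(),
           strongly_convergent = logical(), classification = character(),
           attractor = logical(), grad_resid = numeric())
  } else {
    dplyr::bind_rows(results)
  }
  # merge eradication-frontier points that sit on the same attracting arc
  # (e.g. the two edge crossings around a disease-free pocket at a corner)
  fr_idx <- which(out$classification == "eradication-frontier")
  if (length(fr_idx) > 1) {
    pts <- cbind(out$rJ_star[fr_idx], out$rA_star[fr_idx])
    d <- as.matrix(stats::dist(pts))
    cl <- stats::cutree(stats::hclust(stats::as.dist(d), "single"),
                        h = 0.1)
    merged <- purrr::map(unique(cl), function(ci) {
      sub <- out[fr_idx[cl == ci], ]
      sub$rJ_star[1] <- mean(sub$rJ_star)
      sub$rA_star[1] <- mean(sub$rA_star)
      sub$boundary[1] <- paste(unique(sub$boundary), collapse = "|")
      sub[1, ]
    })
    out <- dplyr::bind_rows(out[-fr_idx, ], merged)
  }
  # deduplicate within 1e-5, keeping the smallest gradient residual
  if (nrow(out) > 1) {
    out <- out |>
      dplyr::arrange(.data$grad_resid) |>
      dplyr::filter(!duplicated(round(cbind(.data$rJ_star, .data$rA_star),
                                      5)))
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(out))) {
        if (j <= i || !keep[j]) next
        if (abs(out$rJ_star[i] - out$rJ_star[j]) < 1e-5 &&
            abs(out$rA_star[i] - out$rA_star[j]) < 1e-5) {
          keep[j] <- FALSE
        }
      }
    }
    out <- out[keep, ]
  }
  # resident equilibrium at each singular point
  if (nrow(out) > 0) {
    eqs <- purrr::map(seq_len(nrow(out)), function(i) {
      eq <- tryCatch(
        solve_equilibrium(p, rJ = out$rJ_star[i], rA = out$rA_star[i]),
        error = function(err) NULL)
      if (is.null(eq)) {
        # right on the epidemic threshold: report the disease-free densities
        e_i <- effective_rates_list(p, out$rJ_star[i], out$rA_star[i])
        dfe <- dfe_core(p, e_i)
        return(tibble(N_star = if (is.null(dfe)) 0 else sum(dfe),
                      I_star = 0,
                      R0 = r0_closed(p, e_i, out$rJ_star[i],
                                     out$rA_star[i])))
      }
      tibble(N_star = sum(eq$state), I_star = eq$state[[3]] + eq$state[[4]],
             R0 = eq$R0)
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(eqs))
    out <- dplyr::arrange(out, dplyr::desc(.data$attractor),
                          .data$rJ_star, .data$rA_star)
  } else {
    sg <- dplyr::mutate(tibble(rJ = grid$rJ, rA = grid$rA),
                        signJ = sign(grid$dwJ), signA = sign(grid$dwA))
    attr(out, "sign_grid") <- sg
  }
  out
}

# Detect an eradication-frontier attractor on one edge of the trait square:
# the point where R0 (closed form along the edge) crosses 1, provided the
# endemic-side selection gradient pushes the free trait toward the frontier
# and the pinned trait's gradient pushes outward. Evolution then drives
# resistance up to the point where the pathogen can no longer persist.
frontier_on_edge <- function(p, spec, delta = 0.01) {
  r0_edge <- function(x) {
    rJ <- if (spec$pin == "rJ") spec$val else x
    rA <- if (spec$pin == "rJ") x else spec$val
    e <- effective_rates_list(p, rJ, rA)
    if (!host_viable(e)) return(NA_real_)
    r0_closed(p, e, rJ, rA)
  }
  r0_lo <- r0_edge(0)
  r0_hi <- r0_edge(1)
  if (is.na(r0_lo) || is.na(r0_hi)) return(NULL)
  if ((r0_lo - 1) * (r0_hi - 1) >= 0) return(NULL)
  x_c <- uniroot(function(x) r0_edge(x) - 1, c(0, 1), tol = 1e-9)$root
  inner <- if (r0_edge(max(x_c - delta, 0)) > 1) x_c - delta else x_c + delta
  if (inner < 0 || inner > 1) return(NULL)
  g <- if (spec$pin == "rJ") grad_at(p, spec$val, inner) else
    grad_at(p, inner, spec$val)
  if (any(!is.finite(g))) return(NULL)
  g_free <- if (spec$pin == "rJ") g[[2]] else g[[1]]
  toward <- sign(x_c - inner)
  if (g_free * toward <= 0) return(NULL)           # flow leaves the frontier
  if (!spec$out(g)) return(NULL)                   # pinned trait not pinned
  pt <- if (spec$pin == "rJ") c(spec$val, x_c) else c(x_c, spec$val)
  tibble(rJ_star = pt[1], rA_star = pt[2],
         boundary = paste0(spec$pin, "=", spec$val, ";R0=1"),
         es_J = NA, es_A = NA, strongly_convergent = NA,
         classification = "eradication-frontier", attractor = TRUE,
         grad_resid = 0)
}

# classify a singular strategy on an edge: the free trait must be both
# convergence stable (decreasing gradient) and uninvadable for an attractor
classify_boundary <- function(params1, p, rJ, rA, spec, gres) {
  free_stage <- if (spec$pin == "rJ") "adult" else "juvenile"
  es <- evolutionary_stability(params1, rJ, rA)
  h <- hess_step
  if (spec$pin == "rJ") {
    g1 <- grad_at(p, rJ, min(rA + h, 1))[[2]]
    g0 <- grad_at(p, rJ, max(rA - h, 0))[[2]]
  } else {
    g1 <- grad_at(p, min(rJ + h, 1), rA)[[1]]
    g0 <- grad_at(p, max(rJ - h, 0), rA)[[1]]
  }
  conv_free <- is.finite(g1) && is.finite(g0) && (g1 - g0) < 0
  es_free <- if (free_stage == "adult") es$es_A else es$es_J
  attract <- conv_free && isTRUE(es_free)
  tibble(rJ_star = rJ, rA_star = rA,
         boundary = paste0(spec$pin, "=", spec$val),
         es_J = es$es_J, es_A = es$es_A,
         strongly_convergent = conv_free,
         classification = if (attract) "boundary-attractor" else
           "boundary-repeller",
         attractor = attract, grad_resid = gres)
}
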