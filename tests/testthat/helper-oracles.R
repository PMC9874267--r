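# Independent oracles, written directly from the model definition (not via
# the package's internals): a hand-coded right-hand side, long-time
# integration to steady state, a numerically assembled next-generation
# matrix, and the linearised growth rate of a rare mutant subpopulation.

oracle_cost <- function(r, c1, c2) {
  if (abs(c2) < 1e-12) c1 * r else c1 * (1 - exp(c2 * r)) / (1 - exp(c2))
}

# effective rates, re-derived from the wiring rules
oracle_rates <- function(pr, rJ = pr$rJ, rA = pr$rA) {
  cj <- oracle_cost(rJ, pr$c1J, pr$c2J)
  ca <- oracle_cost(rA, pr$c1A, pr$c2A)
  a <- pr$a0
  g <- pr$g0
  bJ <- pr$b0
  bA <- pr$b0
  if (pr$juvenile_target == "maturation") g <- pr$g0 * (1 - cj)
  if (pr$juvenile_target == "reproduction") a <- a * (1 - cj)
  if (pr$juvenile_target == "juvenile_mortality") bJ <- pr$b0 * (1 + cj)
  if (pr$adult_target == "reproduction") a <- a * (1 - ca)
  if (pr$adult_target == "adult_mortality") bA <- pr$b0 * (1 + ca)
  list(a = a, g = g, bJ = bJ, bA = bA,
       betaJ = pr$beta0 * (1 - rJ), betaA = pr$beta0 * (1 - rA))
}

# the four ODEs, term by term
oracle_rhs <- function(y, pr, e = oracle_rates(pr)) {
  N <- sum(y)
  It <- y[3] + y[4]
  c(e$a * (1 - pr$q * N) * (y[2] + pr$f * y[4]) -
      (e$bJ + e$g + e$betaJ * It) * y[1],
    e$g * y[1] - (e$bA + e$betaA * It) * y[2],
    e$betaJ * It * y[1] - (e$bJ + e$g + pr$alpha) * y[3],
    e$g * y[3] + e$betaA * It * y[2] - (e$bA + pr$alpha) * y[4])
}

# long-time integration to a steady state from a given start
oracle_steady <- function(pr, y0 = rep(0.1, 4), t_end = 4000) {
  out <- deSolve::lsoda(y0, c(0, t_end),
                        function(t, y, parms) list(oracle_rhs(y, pr)),
                        parms = NULL, rtol = 1e-11, atol = 1e-13)
  as.numeric(out[nrow(out), 2:5])
}

# next-generation matrix R0: F (new infections) and V (transitions) for the
# infected classes (IJ, IA), linearised at the numerically obtained
# disease-free steady state
oracle_r0_ngm <- function(pr) {
  e <- oracle_rates(pr)
  dfe <- oracle_steady(pr, y0 = c(0.1, 0.1, 0, 0))
  stopifnot(dfe[3] < 1e-10, dfe[4] < 1e-10)
  F_mat <- rbind(c(e$betaJ * dfe[1], e$betaJ * dfe[1]),
                 c(e$betaA * dfe[2], e$betaA * dfe[2]))
  V_mat <- rbind(c(e$bJ + e$g + pr$alpha, 0),
                 c(-e$g, e$bA + pr$alpha))
  max(abs(eigen(F_mat %*% solve(V_mat), only.values = TRUE)$values))
}

# dominant eigenvalue of the linearised dynamics of a rare mutant
# subpopulation (SJm, SAm, IJm, IAm) in the resident environment: the
# resident equilibrium supplies N* and the infected pool, the mutant's own
# life-history rates come from its trait value
oracle_mutant_growth <- function(pr, eq_state, stage, rm) {
  rJm <- if (stage == "juvenile") rm else pr$rJ
  rAm <- if (stage == "adult") rm else pr$rA
  em <- oracle_rates(pr, rJm, rAm)
  N <- sum(eq_state)
  It <- eq_state[3] + eq_state[4]
  lJ <- pr$beta0 * (1 - rJm) * It
  lA <- pr$beta0 * (1 - rAm) * It
  fac <- em$a * (1 - pr$q * N)
  M <- rbind(c(-(em$bJ + em$g + lJ), fac, 0, fac * pr$f),
             c(em$g, -(em$bA + lA), 0, 0),
             c(lJ, 0, -(em$bJ + em$g + pr$alpha), 0),
             c(0, lA, em$g, -(em$bA + pr$alpha)))
  max(Re(eigen(M, only.values = TRUE)$values))
}

# one-row parameter list from a host_params tibble row (test-side currency)
prow <- function(params, i = 1) as.list(params[i, ])
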