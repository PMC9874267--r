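fig3a_params <- host_params(beta0 = 8, f = 0.1, alpha = 0,
                            juvenile_target = "juvenile_mortality",
                            adult_target = "reproduction")

test_that("ode_rhs vanishes at extinction and at the disease-free state", {
  p <- host_params()
  expect_equal(unlist(ode_rhs(data.frame(SJ = 0, SA = 0, IJ = 0, IA = 0),
                              p)),
               c(dSJ = 0, dSA = 0, dIJ = 0, dIA = 0))
  dfe <- disease_free_equilibrium(p)
  d <- ode_rhs(dfe[, c("SJ", "SA", "IJ", "IA")], p)
  expect_lt(max(abs(unlist(d))), 1e-12)
})

test_that("ode_rhs matches a term-by-term independent evaluation", {
  p <- host_params(beta0 = 8, f = 1, alpha = 0)
  y <- c(SJ = 0.2, SA = 0.2, IJ = 0.1, IA = 0.1)
  got <- unlist(ode_rhs(as.data.frame(t(y)), p))
  # hand evaluation: N = 0.6, I = 0.2, lambda = 1.6, birth = 5*0.4*0.3 = 0.6
  expect_equal(unname(got),
               c(0.6 - (1 + 1 + 1.6) * 0.2,
                 0.2 - (1 + 1.6) * 0.2,
                 1.6 * 0.2 - 2 * 0.1,
                 0.1 + 1.6 * 0.2 - 0.1),
               tolerance = 1e-12)
  # and against the helper oracle on a random draw
  pr <- prow(sample_params(1, seed = 5))
  y2 <- runif(4, 0.01, 0.4)
  got2 <- unlist(ode_rhs(as.data.frame(t(setNames(y2, names(y)))),
                         sample_params(1, seed = 5)))
  expect_equal(unname(got2), oracle_rhs(y2, pr), tolerance = 1e-10)
  expect_error(ode_rhs(data.frame(SJ = -1, SA = 0, IJ = 0, IA = 0),
                       host_params()),
               class = "ageresist_param_error")
})

test_that("closed-form disease-free equilibrium matches integrated dynamics", {
  # defaults: (SJ*, SA*) = (0.3, 0.3)
  dfe <- disease_free_equilibrium(host_params())
  expect_equal(dfe$SJ, 0.3, tolerance = 1e-12)
  expect_equal(dfe$SA, 0.3, tolerance = 1e-12)
  # property: agreement with long-time disease-free integration
  params <- sample_params(25, seed = 101, endemic_only = FALSE)
  dfe <- disease_free_equilibrium(params)
  for (i in seq_len(nrow(params))) {
    if (dfe$kind[i] != "disease_free") next
    steady <- oracle_steady(prow(params, i), y0 = c(0.1, 0.1, 0, 0))
    expect_lt(max(abs(steady[1:2] - c(dfe$SJ[i], dfe$SA[i]))), 1e-6)
    expect_lt(dfe$residual[i], 1e-10)
  }
})

test_that("host non-viability is reported as extinction", {
  # ag <= bA (bJ + g): a0 = 1, g0 = 1, b0 = 1 gives surplus 1 - 2 < 0
  out <- disease_free_equilibrium(host_params(a0 = 1))
  expect_equal(out$kind, "extinct")
  expect_equal(out$N, 0)
})

test_that("closed-form R0 agrees with the next-generation oracle", {
  expect_equal(r0(host_params(beta0 = 8))$R0, 4.8, tolerance = 1e-12)
  params <- sample_params(25, seed = 7, endemic_only = FALSE)
  vals <- r0(params)$R0
  for (i in seq_len(nrow(params))) {
    if (is.na(vals[i])) next
    expect_equal(vals[i], oracle_r0_ngm(prow(params, i)),
                 tolerance = 1e-8)
  }
})

test_that("R0 is zero at full resistance and linear in beta0", {
  p <- host_params(juvenile_target = "juvenile_mortality",
                   adult_target = "adult_mortality", rJ = 1, rA = 1)
  expect_equal(r0(p)$R0, 0)
  p1 <- host_params(beta0 = 3)
  p2 <- host_params(beta0 = 9)
  expect_equal(3 * r0(p1)$R0, r0(p2)$R0, tolerance = 1e-12)
})

test_that("R0 is non-increasing in each resistance trait", {
  base <- host_params(beta0 = 8, juvenile_target = "maturation")
  rr <- seq(0, 1, by = 0.1)
  rj_path <- r0(dplyr::mutate(base[rep(1, length(rr)), ], rJ = rr))$R0
  ra_path <- r0(dplyr::mutate(base[rep(1, length(rr)), ], rA = rr))$R0
  expect_true(all(diff(rj_path) < 1e-12))
  expect_true(all(diff(ra_path) < 1e-12))
})

test_that("endemic equilibrium is positive, sharp and stable when R0 > 1", {
  p <- host_params(beta0 = 8, f = 0.1)
  eq <- endemic_equilibrium(p)
  expect_equal(eq$kind, "endemic")
  expect_true(all(c(eq$SJ, eq$SA, eq$IJ, eq$IA) > 0))
  expect_lt(eq$residual, 1e-9)
  expect_true(eq$stable)
  # and matches the long-time integration oracle
  steady <- oracle_steady(prow(p))
  expect_lt(max(abs(steady - c(eq$SJ, eq$SA, eq$IJ, eq$IA))), 1e-6)
})

test_that("below the epidemic threshold the disease-free state is returned", {
  eq <- endemic_equilibrium(host_params(beta0 = 0.1))
  expect_equal(eq$kind, "disease_free")
  expect_equal(eq$I, 0)
  expect_true(eq$stable)
})

test_that("multistart guard reports a single endemic equilibrium here", {
  eq <- endemic_equilibrium(fig3a_params, multistart = TRUE)
  expect_equal(eq$n_equilibria, 1)
})

test_that("infected density vanishes continuously at the R0 = 1 threshold", {
  # defaults with f = 1, alpha = 0: critical beta0 solves R0 = 0.6 beta0 = 1
  p <- host_params(f = 1, alpha = 0)
  betas <- 5 / 3 + c(0.05, 0.02, 0.01)
  infected <- vapply(betas, function(b) {
    endemic_equilibrium(dplyr::mutate(p, beta0 = b))$I
  }, numeric(1))
  expect_true(all(diff(infected) < 0))
  expect_lt(infected[3], 0.01)
})

test_that("rescaling q and b0 reproduces equilibria (non-dimensionalisation)", {
  set.seed(31)
  for (k in 1:10) {
    q <- runif(1, 0.3, 3)
    b0 <- runif(1, 0.3, 3)
    pr <- sample_params(1, seed = 300 + k)
    orig <- dplyr::mutate(pr, q = .env$q, b0 = .env$b0,
                          a0 = .data$a0 * .env$b0, g0 = .data$g0 * .env$b0,
                          alpha = .data$alpha * .env$b0,
                          beta0 = .data$beta0 * .env$q * .env$b0)
    scaled <- dplyr::mutate(pr, q = 1, b0 = 1)
    eq_orig <- endemic_equilibrium(orig)
    eq_scaled <- endemic_equilibrium(scaled)
    expect_equal(eq_orig$kind, eq_scaled$kind)
    expect_equal(r0(orig)$R0, r0(scaled)$R0, tolerance = 1e-10)
    if (eq_orig$kind == "endemic") {
      expect_equal(q * c(eq_orig$SJ, eq_orig$SA, eq_orig$IJ, eq_orig$IA),
                   c(eq_scaled$SJ, eq_scaled$SA, eq_scaled$IJ,
                     eq_scaled$IA),
                   tolerance = 1e-7)
    }
  }
})

test_that("ecology_dynamics integrates trajectories with conserved signs", {
  traj <- ecology_dynamics(fig3a_params, times = seq(0, 50, 5))
  expect_equal(nrow(traj), 11)
  expect_true(all(traj[, c("SJ", "SA", "IJ", "IA")] >= 0))
  expect_equal(traj$N, traj$SJ + traj$SA + traj$IJ + traj$IA)
})
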