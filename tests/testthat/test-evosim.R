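fig3a <- host_params(beta0 = 8, f = 0.1, alpha = 0,
                     juvenile_target = "juvenile_mortality",
                     adult_target = "reproduction")

test_that("one phenotype without mutation reproduces the endemic equilibrium", {
  sim <- simulate_evolution(fig3a, rJ_init = 0.2, rA_init = 0.4,
                            n_events = 3, seed = 1, eco_window = 2000,
                            intro_density = 0,
                            ode_rtol = 1e-11, ode_atol = 1e-13)
  eq <- endemic_equilibrium(dplyr::mutate(fig3a, rJ = 0.2, rA = 0.4))
  fin <- sim$final_phenotypes
  expect_equal(nrow(fin), 1)
  expect_lt(max(abs(c(fin$SJ, fin$SA, fin$IJ, fin$IA) -
                      c(eq$SJ, eq$SA, eq$IJ, eq$IA))), 1e-8)
  # monomorphic throughout: zero trait variance
  expect_true(all(tidy(sim)$var_rJ == 0))
  expect_true(all(tidy(sim)$var_rA == 0))
})

test_that("simulations are deterministic given the seed", {
  s1 <- simulate_evolution(fig3a, n_events = 25, seed = 9)
  s2 <- simulate_evolution(fig3a, n_events = 25, seed = 9)
  expect_identical(tidy(s1), tidy(s2))
  s3 <- simulate_evolution(fig3a, n_events = 25, seed = 10)
  expect_false(identical(tidy(s1), tidy(s3)))
  expect_s3_class(autoplot(s1), "ggplot")
})

test_that("traits stay on the grid and inside the unit square", {
  sim <- simulate_evolution(fig3a, n_events = 40, seed = 3, step = 0.05)
  traits <- unique(c(sim$trajectory$rJ, sim$trajectory$rA))
  expect_true(all(traits >= 0 & traits <= 1))
  expect_true(all(abs(traits / 0.05 - round(traits / 0.05)) < 1e-9))
  g <- glance(sim)
  expect_true(g$final_rJ >= 0 && g$final_rJ <= 1)
})

test_that("without trade-offs resistance fixes at its maximum", {
  # transmissibility high enough that the disease stays endemic all the way
  # to full resistance (otherwise selection stops at the eradication
  # frontier where R0 falls below 1)
  p <- host_params(beta0 = 200, f = 0.2, c1J = 0, c1A = 0)
  sim <- simulate_evolution(p, rJ_init = 0.5, rA_init = 0.5,
                            n_events = 600, seed = 5, step = 0.05)
  g <- glance(sim)
  expect_gt(g$final_rJ, 0.95)
  expect_gt(g$final_rA, 0.95)
})

test_that("results are robust to halving introduction density and cull threshold", {
  finals <- lapply(list(c(1e-4, 1e-5), c(5e-5, 5e-6)), function(v) {
    sim <- simulate_evolution(fig3a, rJ_init = 0.3, rA_init = 0.3,
                              n_events = 400, seed = 17,
                              intro_density = v[1],
                              extinct_threshold = v[2])
    unname(sim$final_mean)
  })
  expect_lt(max(abs(finals[[1]] - finals[[2]])), 0.06)
})

test_that("trait distribution summary flags modality sensibly", {
  sim <- simulate_evolution(fig3a, n_events = 60, seed = 2)
  tds <- trait_distribution_summary(sim)
  expect_equal(nrow(tds$series), sim$n_events)
  # near-monomorphic evolution: no sustained bimodality
  expect_false(any(tds$sustained_bimodality))
  expect_true(all(tds$series$modes_rJ >= 1))
  expect_error(trait_distribution_summary(list()),
               class = "ageresist_param_error")
})
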