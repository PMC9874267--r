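test_that("sweep input validation catches malformed specs", {
  p <- host_params()
  expect_error(run_sweep(p, "virulence", c(0, 1)),
               class = "ageresist_config_error")
  expect_error(run_sweep(p, "f", c(0.1, 0.5, 0.3)),
               class = "ageresist_config_error")
})

test_that("a short sterility sweep tracks attractors and densities", {
  base <- host_params(beta0 = 8, alpha = 0,
                      juvenile_target = "juvenile_mortality",
                      adult_target = "reproduction")
  sw <- run_sweep(base, "f", c(0.9, 0.5, 0.1), mode = "continuation")
  expect_s3_class(sw, "sweep_result")
  att <- sw[sw$attractor %in% TRUE, ]
  expect_true(all(att$status == "ok"))
  # each attractor row carries its resident densities
  expect_true(all(att$N_star > 0))
  # low virulence: no resistance; high virulence: resistance evolves
  low <- att[att$f == 0.9, ]
  high <- att[att$f == 0.1, ]
  expect_true(all(low$rJ_star + low$rA_star < 0.2))
  expect_true(any(high$rJ_star + high$rA_star > 0.5))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("continuation and global modes agree on a single attractor", {
  base <- host_params(beta0 = 8, alpha = 0,
                      juvenile_target = "juvenile_mortality",
                      adult_target = "reproduction")
  vals <- c(0.3, 0.1)
  cont <- run_sweep(base, "f", vals, mode = "continuation")
  glob <- run_sweep(base, "f", vals, mode = "global")
  for (v in vals) {
    a1 <- cont[cont$f == v & cont$attractor %in% TRUE, ]
    a2 <- glob[glob$f == v & glob$attractor %in% TRUE, ]
    expect_equal(nrow(a1), nrow(a2))
    expect_equal(a1$rJ_star, a2$rJ_star, tolerance = 1e-5)
    expect_equal(a1$rA_star, a2$rA_star, tolerance = 1e-5)
  }
})

test_that("sweep output is reproducible run to run", {
  base <- host_params(beta0 = 8, alpha = 0)
  s1 <- run_sweep(base, "f", c(0.5, 0.2))
  s2 <- run_sweep(base, "f", c(0.5, 0.2))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("low transmissibility gives one zero-resistance attractor, no bistability", {
  base <- host_params(alpha = 0, f = 0.5,
                      juvenile_target = "juvenile_mortality",
                      adult_target = "adult_mortality")
  bi <- detect_bistability(base, "beta0", c(0.5, 1.2, 2), grid_n = 4)
  expect_true(all(!bi$by_value$bistable))
  expect_true(all(bi$by_value$n_attractors == 1))
  att <- bi$sweep[bi$sweep$attractor %in% TRUE, ]
  expect_true(all(att$rJ_star == 0 & att$rA_star == 0))
  expect_equal(nrow(bi$regions), 0)
})

test_that("extreme transmissibility is detected as bistable, without stage divergence", {
  base <- host_params(alpha = 0, f = 0.5,
                      juvenile_target = "juvenile_mortality",
                      adult_target = "adult_mortality")
  bi <- detect_bistability(base, "beta0", c(800, 1000), grid_n = 5)
  expect_true(all(bi$by_value$bistable))
  expect_false(any(bi$by_value$divergent_stages))
  expect_gt(nrow(bi$regions), 0)
})
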