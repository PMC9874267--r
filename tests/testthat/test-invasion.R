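fig3a <- host_params(beta0 = 8, f = 0.1, alpha = 0,
                     juvenile_target = "juvenile_mortality",
                     adult_target = "reproduction")

test_that("a mutant identical to the resident is exactly neutral", {
  params <- sample_params(20, seed = 21)
  for (i in seq_len(nrow(params))) {
    ctx <- resident_context(params[i, ])
    wJ <- invasion_fitness(ctx, "juvenile", params$rJ[i])$fitness
    wA <- invasion_fitness(ctx, "adult", params$rA[i])$fitness
    expect_lt(abs(wJ), 1e-10)
    expect_lt(abs(wA), 1e-10)
  }
})

test_that("fitness sign matches the linearised mutant growth-rate oracle", {
  params <- sample_params(30, seed = 22)
  set.seed(22)
  agree <- 0
  total <- 0
  for (i in seq_len(nrow(params))) {
    ctx <- resident_context(params[i, ])
    eq_state <- as.numeric(tidy(ctx)[1, c("SJ", "SA", "IJ", "IA")])
    for (stage in c("juvenile", "adult")) {
      rm <- runif(1)
      w <- invasion_fitness(ctx, stage, rm)$fitness
      lam <- oracle_mutant_growth(prow(params, i), eq_state, stage, rm)
      total <- total + 1
      if (sign(w) == sign(lam) || abs(w) < 1e-6) agree <- agree + 1
    }
  }
  expect_equal(agree, total)
})

test_that("juvenile resistance is selected upward from zero in the CSS case", {
  ctx <- resident_context(fig3a)  # resident rJ = rA = 0
  w_small <- invasion_fitness(ctx, "juvenile", 0.05)$fitness
  expect_gt(w_small, 0)
  g <- selection_gradients(fig3a)
  expect_gt(g$dwJ, 0)
})

test_that("invasion fitness requires an endemic resident", {
  expect_error(resident_context(host_params(beta0 = 0.5)),
               class = "ageresist_domain_error")
  expect_error(invasion_fitness(host_params(a0 = 1), "adult", 0.5))
})

test_that("without trade-offs resistance is always favoured", {
  p <- host_params(beta0 = 8, f = 0.2, c1J = 0, c1A = 0,
                   rJ = 0.3, rA = 0.4)
  g <- selection_gradients(p)
  expect_gt(g$dwJ, 0)
  expect_gt(g$dwA, 0)
})

test_that("with costs but no virulence resistance is selected against", {
  for (jt in c("maturation", "juvenile_mortality", "reproduction")) {
    p <- host_params(beta0 = 8, f = 1, alpha = 0, juvenile_target = jt,
                     rJ = 0.3, rA = 0.3)
    g <- selection_gradients(p)
    expect_lt(g$dwJ, 0)
    expect_lt(g$dwA, 0)
  }
})

test_that("selection gradients vanish at the co-singular strategy", {
  sing <- find_cosingular(fig3a)
  expect_equal(nrow(sing), 1)
  expect_equal(sing$classification, "CSS")
  expect_true(sing$attractor)
  expect_true(sing$es_J && sing$es_A && sing$strongly_convergent)
  g <- selection_gradients(dplyr::mutate(fig3a, rJ = sing$rJ_star,
                                         rA = sing$rA_star))
  expect_lt(abs(g$dwJ), 1e-7)
  expect_lt(abs(g$dwA), 1e-7)
})

test_that("stability classification is robust to halving the FD step", {
  sing <- find_cosingular(fig3a)
  for (h in c(1e-4, 5e-5)) {
    es <- evolutionary_stability(fig3a, sing$rJ_star, sing$rA_star, h = h)
    cv <- convergence_stability(fig3a, sing$rJ_star, sing$rA_star, h = h)
    expect_true(es$es_J && es$es_A)
    expect_true(cv$strongly_convergent)
    expect_lt(cv$eig1, 0)
  }
})

test_that("no virulence gives a unique zero-resistance attractor", {
  for (at in c("reproduction", "adult_mortality")) {
    p <- host_params(beta0 = 8, f = 1, alpha = 0,
                     juvenile_target = "juvenile_mortality",
                     adult_target = at)
    sing <- find_cosingular(p)
    att <- sing[sing$attractor %in% TRUE, ]
    expect_equal(nrow(att), 1)
    expect_equal(c(att$rJ_star, att$rA_star), c(0, 0))
  }
})

test_that("the high-transmissibility regime is bistable", {
  p <- host_params(beta0 = 1000, f = 0.5, alpha = 0,
                   juvenile_target = "juvenile_mortality",
                   adult_target = "adult_mortality")
  sing <- find_cosingular(p)
  att <- sing[sing$attractor %in% TRUE, ]
  expect_equal(nrow(att), 2)
  att <- att[order(att$rJ_star), ]
  expect_equal(c(att$rJ_star[1], att$rA_star[1]), c(0, 0))
  expect_true(att$rJ_star[2] > 0.9 && att$rA_star[2] > 0.9)
})

test_that("phase plane has one basin in the CSS case", {
  pp <- phase_plane(fig3a, grid_n = 9)
  gl <- glance(pp)
  expect_equal(gl$n_attractors, 1)
  expect_equal(gl$n_basins, 1)
  expect_true(all(stats::na.omit(tidy(pp)$basin) == 1))
  expect_gt(nrow(pp$nullclines), 0)
  expect_s3_class(autoplot(pp), "ggplot")
})

test_that("phase plane has two basins separated in the bistable case", {
  p <- host_params(beta0 = 1000, f = 0.5, alpha = 0,
                   juvenile_target = "juvenile_mortality",
                   adult_target = "adult_mortality")
  pp <- phase_plane(p, grid_n = 9)
  gl <- glance(pp)
  expect_equal(gl$n_attractors, 2)
  expect_equal(gl$n_basins, 2)
})

test_that("lattice gradient signs agree with pairwise invasibility checks", {
  pp <- phase_plane(fig3a, grid_n = 5, basins = FALSE)
  grid <- tidy(pp)
  grid <- grid[grid$status == "endemic" &
                 grid$rJ > 0.05 & grid$rJ < 0.95 &
                 grid$rA > 0.05 & grid$rA < 0.95, ]
  for (i in seq_len(nrow(grid))) {
    ctx <- resident_context(dplyr::mutate(fig3a, rJ = grid$rJ[i],
                                          rA = grid$rA[i]))
    wup <- invasion_fitness(ctx, "juvenile", grid$rJ[i] + 0.01)$fitness
    wdn <- invasion_fitness(ctx, "juvenile", grid$rJ[i] - 0.01)$fitness
    # the uphill mutant of a non-singular resident invades
    if (abs(grid$dwJ[i]) > 1e-3) {
      expect_equal(sign(if (grid$dwJ[i] > 0) wup else wdn), 1)
    }
  }
})

test_that("resident context stores consistent forces of infection", {
  ctx <- resident_context(dplyr::mutate(fig3a, rJ = 0.3, rA = 0.2))
  td <- tidy(ctx)
  expect_equal(td$lambdaJ, 8 * (1 - 0.3) * td$I, tolerance = 1e-12)
  expect_equal(td$lambdaA, 8 * (1 - 0.2) * td$I, tolerance = 1e-12)
  expect_equal(glance(ctx)$N, td$N)
})
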