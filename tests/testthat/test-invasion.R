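test_that("invasion fitness is exactly neutral on the diagonal", {
  p <- sim_params()
  st <- resident_market_stats(10, p, mode = "balance")
  for (T in c(2, 5, 10, 20)) {
    expect_equal(invasion_fitness(T, T, p, st), 1)
  }
})

test_that("selection pushes care downward from the egalitarian start", {
  p <- sim_params()
  # resident 20: a mutant caring less invades, one caring more does not
  st <- resident_market_stats(20, p, mode = "balance")
  expect_gt(invasion_fitness(15, 20, p, st), 1)
  expect_lt(invasion_fitness(21, 20, p, st), 1)
  # consistent with the stochastic engine: mean care declines from (20, 20)
  tr <- baseline_run()
  expect_lt(tr$summary$care_f_mean[100], 19)
})

test_that("the singular strategy sits at care level 5 and is a branching point", {
  p <- sim_params()
  bal <- find_singular_strategy(p, range = 1:15, mode = "balance")
  expect_true(abs(bal$T_star - 5) <= 1)
  expect_equal(bal$type, "branching")
  sim <- find_singular_strategy(update_params(p, gamma = 0.012,
                                              n0_per_sex = 500, seed = 61),
                                range = 2:10, mode = "simulate",
                                burnin_days = 2000, window_days = 3000)
  expect_true(abs(sim$T_star - 5) <= 1)
  expect_equal(sim$type, "branching")
  # disruptive regime at the singular point: both cheaper and costlier
  # mutants do at least as well as the resident
  st5 <- resident_market_stats(bal$T_star, p, mode = "balance")
  expect_gt(invasion_fitness(bal$T_star - 1, bal$T_star, p, st5), 1 - 0.02)
  expect_gt(invasion_fitness(bal$T_star + 1, bal$T_star, p, st5), 1 - 0.02)
})

test_that("the singular strategy rises with the survival benchmark B", {
  p20 <- sim_params()
  p40 <- sim_params(B = 40)
  t20 <- find_singular_strategy(p20, range = 1:25, mode = "balance")$T_star
  t40 <- find_singular_strategy(p40, range = 1:25, mode = "balance")$T_star
  expect_gt(t40, t20)
})

test_that("balance and simulated market statistics agree for a short-cycle resident", {
  p <- sim_params()
  bal <- resident_market_stats(5, p, mode = "balance")
  # the balance mode models the daily-noise market but not the slow
  # stochastic sex-ratio queue, which only the momentarily surplus sex
  # feels; compare against the deficit side, which the balance predicts
  sims <- sapply(1:3, function(k) {
    st <- resident_market_stats(
      5, update_params(p, gamma = 0.012, n0_per_sex = 500, seed = 40 + k),
      mode = "simulate", burnin_days = 2000, window_days = 2000)
    max(st$m_f, st$m_m)
  })
  tol <- max(3 * stats::sd(sims) / sqrt(3), 0.02)
  expect_lt(abs(bal$m_f - mean(sims)), tol)
  # an unsustainable resident (no care at all) is reported, not an error
  dead <- resident_market_stats(0, p, mode = "balance")
  expect_true(dead$extinct)
})

test_that("the invasion grid is oriented and neutral on its diagonal", {
  p <- sim_params()
  g <- invasion_grid(p, residents = c(4, 5, 6), mutants = c(4, 5, 6),
                     mode = "balance")
  expect_equal(dim(g), c(3, 3))
  expect_true(all(abs(diag(g) - 1) < 1e-12))
})
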