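# The renewal fitness-profile estimator, checked against closed-form limits
# and the engine-based phantom-probe Monte Carlo.

hand_market <- function(m = 1, partner = 2, N = 2000) {
  structure(list(m_f = m, m_m = m, N_bar = N, pref_bar = 0, orn_bar = 0,
                 partner_f = partner, partner_m = partner, window = 1),
            class = "sexrole_market")
}

test_that("the renewal profile reduces to the uniparental benchmark in the no-partner limit", {
  # instant mating, partner provides no care: lifetime reproductive success
  # is S(T) times the expected number of matings, whose optimum sits at the
  # benchmark B (the engine's one-day re-mating lag shifts it by < 1 day)
  p <- sim_params(gamma = 0)
  pr <- estimate_fitness_profile(hand_market(m = 1, partner = 0, N = 0),
                                 sex = "F", grid = 0:60, params = p)
  expect_lt(abs(pr$care[which.max(pr$lrs)] - 20), 2)
  # and the optimum scales with B
  p40 <- sim_params(B = 40, gamma = 0)
  pr40 <- estimate_fitness_profile(hand_market(m = 1, partner = 0, N = 0),
                                   sex = "F", grid = 0:80, params = p40)
  expect_lt(abs(pr40$care[which.max(pr40$lrs)] - 40), 3)
})

test_that("profiles are finite, non-negative, and fail loudly without mortality", {
  p <- sim_params()
  pr <- estimate_fitness_profile(hand_market(), "M", 0:20, p)
  expect_true(all(is.finite(pr$lrs)) && all(pr$lrs >= 0))
  deathless <- sim_params(mortality = 0)
  expect_error(
    estimate_fitness_profile(hand_market(), "F", 0:5, deathless),
    "mortality")
})

test_that("renewal estimates agree with phantom-probe Monte Carlo on a frozen population", {
  # monomorphic biased population, mutation off; compare on a coarse grid
  p <- sim_params(seed = 31, gamma = 0.006, mu = 0, n0_per_sex = 1000,
                  init_careF = 18, init_careM = 2)
  pop <- new_population(p)
  step_days(pop, 3000, record_every = 0)
  step_days(pop, 2000, record_every = 500)
  rec <- sexrolesim:::collect_records(pop)
  tr <- sexrolesim:::new_trajectory(p, rec$summary, rec$hist_f, rec$hist_m,
                                    FALSE, 5000, pop = pop)
  st <- market_stats(tr, window = 4)
  grid <- c(0, 5, 10, 18)
  pr <- estimate_fitness_profile(st, "F", grid, p)
  mc <- probe_fitness_mc(pop, "F", grid, n_probe = 80, seed = 99)
  z <- (pr$lrs - mc$lrs) / mc$se
  expect_true(all(abs(z) < 3))
})

test_that("market statistics summarise matings per searcher-day", {
  p <- sim_params(seed = 4, gamma = 0.024, n0_per_sex = 250, mu = 0,
                  init_careF = 10, init_careM = 10)
  tr <- run_simulation(p, generations = 4, keep_pop = TRUE)
  st <- market_stats(tr, window = 2)
  s <- utils::tail(tr$summary, 2)
  expect_equal(st$m_f, sum(s$matings) / sum(s$search_days_f))
  expect_equal(st$m_m, sum(s$matings) / sum(s$search_days_m))
  expect_true(all(st$partner_f >= 0))
  # without the live population the partner sample is unavailable
  tr$pop <- NULL
  expect_error(market_stats(tr, window = 2), "clutch log")
})
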