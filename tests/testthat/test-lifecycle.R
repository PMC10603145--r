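test_that("mortality-free populations persist unchanged through the day", {
  p <- deathless_params(n0_per_sex = 40)
  pop <- new_population(p, individuals = tiny_population())
  before <- get_individuals(pop)
  step_phase(pop, "mortality")
  expect_identical(nrow(get_individuals(pop)), nrow(before))
})

test_that("daily deaths are binomial at the state mortality", {
  p <- sim_params(mortality = 0.001, mu = 0, n0_per_sex = 50000, gamma = 0,
                  seed = 42)
  pop <- new_population(p)
  n0 <- population_size(pop)
  step_phase(pop, "mortality")
  deaths <- n0 - population_size(pop)
  expect_lt(abs(deaths - n0 * 0.001), 3 * sqrt(n0 * 0.001 * 0.999))
})

test_that("expected lifespan at 0.001 per day is 1000 days", {
  # mortality-only cohort: a single-sex population has no matings, so the
  # only events are deaths; total person-days / cohort size = mean lifespan
  n0 <- 20000
  ind <- data.frame(sex = "F", state = "search", days_left = 0L,
                    careF = 0L, careM = 0L, pref = 0, orn = 0)
  ind <- ind[rep(1, n0), ]
  p <- sim_params(seed = 9, mu = 0)
  pop <- new_population(p, individuals = ind)
  step_days(pop, 12000, record_every = 1)  # 12 expected lifespans
  s <- sexrolesim:::collect_records(pop)$summary
  expect_equal(utils::tail(s$n, 1), 0)     # cohort exhausted
  lifespan <- sum(s$n) / n0 + 0.5          # survivors counted at day end
  se <- 1000 / sqrt(n0)
  expect_lt(abs(lifespan - 1000), 3 * se)
})

test_that("a caring pair cycles with period equal to care duration plus one", {
  p <- deathless_params(n0_per_sex = 1, gamma = 0)
  pop <- new_population(p, individuals = pair_population(3, 5))
  mate_days <- integer(0)
  for (d in 1:20) {
    step_phase(pop, "day")
    df <- get_individuals(pop)
    if (all(df$state == "caring") &&
        any(df$days_left[df$sex == "M"] == 5)) {
      mate_days <- c(mate_days, current_day(pop))
    }
  }
  # male care 5: re-mating every 6 days (care + 1 search day)
  expect_equal(mate_days[1], 1)
  expect_equal(diff(mate_days)[1], 5 + 1)
})

test_that("clutches resolve the day the longest carer finishes", {
  p <- deathless_params(n0_per_sex = 1, gamma = 0)
  pop <- new_population(p, individuals = pair_population(3, 5))
  step_phase(pop, "day")  # mating on day 1
  expect_equal(nrow(get_clutches(pop)), 1)
  cl <- get_clutches(pop)
  expect_equal(cl$mating_day, 1)
  expect_equal(cl$intendedF, 3)
  expect_equal(cl$intendedM, 5)
  resolved_day <- NA
  for (d in 2:10) {
    step_phase(pop, "day")
    if (nrow(clutch_log(pop)) == 1) { resolved_day <- current_day(pop); break }
  }
  expect_equal(resolved_day, 1 + max(3, 5))
  log <- clutch_log(pop)
  expect_equal(log$realizedF, 3)
  expect_equal(log$realizedM, 5)
  # the female parent finished earlier and is already searching again
  df <- get_individuals(pop)
  expect_equal(as.character(df$state[df$sex == "F" & df$careF == 3]), "search")
})

test_that("a parent with intended care zero searches again the day after mating", {
  p <- deathless_params(n0_per_sex = 1, gamma = 0)
  pop <- new_population(p, individuals = pair_population(0, 4))
  step_phase(pop, "day")  # mate on day 1
  df <- get_individuals(pop)
  expect_equal(as.character(df$state[df$sex == "F"]), "caring")
  step_phase(pop, "day")  # day 2: transition without having cared
  df <- get_individuals(pop)
  expect_equal(as.character(df$state[df$sex == "F"]), "search")
  # the clutch still waits for the male; realized female care is 0
  cl <- get_clutches(pop)
  expect_equal(cl$realizedF, 0)
  expect_equal(cl$remaining, 1)
})

test_that("a widowed parent finishes alone; the dead parent's realized care is its days since mating", {
  m <- matrix(0, 2, 4)
  m[2, 4] <- 1  # males die with certainty while caring
  p <- sim_params(mortality = m, mu = 0, beta = 0, n0_per_sex = 1, gamma = 0)
  pop <- new_population(p, individuals = pair_population(18, 5))
  step_phase(pop, "day")  # mate day 1
  step_phase(pop, "day")  # day 2: father dies at the start of the day
  df <- get_individuals(pop)
  expect_equal(nrow(df), 1)
  expect_equal(as.character(df$sex), "F")
  cl <- get_clutches(pop)
  expect_equal(cl$realizedM, 1)  # one day from mating to death
  expect_equal(cl$remaining, 1)
  for (d in 3:25) step_phase(pop, "day")
  log <- clutch_log(pop)
  expect_equal(nrow(log), 1)
  expect_equal(log$day, 1 + 18)  # resolves when the mother finishes
  expect_equal(log$realizedF, 18)
  expect_equal(log$realizedM, 1)
})

test_that("juveniles enter the pre-mating state exactly at maturation", {
  p <- deathless_params(n0_per_sex = 1, gamma = 0)
  ind <- data.frame(sex = "F", state = "juvenile", days_left = 20L,
                    careF = 5L, careM = 5L, pref = 0, orn = 0)
  pop <- new_population(p, individuals = ind)
  for (d in 1:19) {
    step_phase(pop, "day")
    expect_equal(as.character(get_individuals(pop)$state), "juvenile")
  }
  step_phase(pop, "day")  # day 20: matures, passes straight to search
  expect_equal(as.character(get_individuals(pop)$state), "search")
})

test_that("the mating round pairs each searcher at most once", {
  # 100 searching females, 50 searching males, female choice at p = s = 0:
  # each male has at most one encounter, accepted with probability 0.98
  pairs <- replicate(40, {
    ind <- data.frame(
      sex = rep(c("F", "M"), c(100, 50)), state = "search", days_left = 0L,
      careF = 5L, careM = 5L, pref = 0, orn = 0)
    p <- deathless_params(n0_per_sex = 1, mate_choice = TRUE,
                          seed = sample.int(1e6, 1))
    pop <- new_population(p, individuals = ind)
    step_phase(pop, "mating")
    sum(get_individuals(pop)$state == "caring") / 2
  })
  expect_true(all(pairs <= 50))
  expected <- 50 * acceptance_probability(0, 0)
  se <- sqrt(50 * 0.9804 * 0.0196 / 40)
  expect_lt(abs(mean(pairs) - expected), 3 * se)
})

test_that("one female and one male always pair under random mating", {
  p <- deathless_params(n0_per_sex = 1, gamma = 0)
  pop <- new_population(p, individuals = pair_population(2, 2))
  step_phase(pop, "mating")
  expect_equal(sum(get_individuals(pop)$state == "caring"), 2)
})

test_that("trajectories are reproducible from the seed and extinction is flagged", {
  p <- sim_params(seed = 77, gamma = 0.05, n0_per_sex = 60)
  a <- run_simulation(p, generations = 3, record_every = 250)
  b <- run_simulation(p, generations = 3, record_every = 250)
  expect_identical(a$summary, b$summary)
  expect_identical(a$hist_f, b$hist_f)
  # certain death wipes the population and sets the flag, without error
  pdead <- sim_params(mortality = 1, n0_per_sex = 20)
  tr <- run_simulation(pdead, generations = 1, record_every = 1)
  expect_true(tr$extinct)
  expect_equal(utils::tail(tr$summary$n, 1), 0)
})

test_that("the daily ledger balances: population changes by recruits minus deaths", {
  p <- sim_params(seed = 5, gamma = 0.05, n0_per_sex = 100)
  pop <- new_population(p)
  step_days(pop, 400, record_every = 1)
  s <- sexrolesim:::collect_records(pop)$summary
  dn <- diff(s$n)
  expect_equal(dn, (s$recruits - s$deaths)[-1])
})

test_that("with equal mortalities and random mating the adult sex ratio stays near 1:1", {
  tr <- baseline_run()
  w <- utils::tail(tr$summary, 100)
  frac_f <- sum(w$n_f) / sum(w$n)
  expect_lt(abs(frac_f - 0.5), 0.05)
})

test_that("with mutation off no new care alleles ever appear", {
  ind <- data.frame(
    sex = rep(c("F", "M"), each = 100), state = "search", days_left = 0L,
    careF = rep(c(10L, 20L), 100), careM = rep(c(10L, 20L), 100),
    pref = 0, orn = 0)
  p <- sim_params(seed = 3, mu = 0, gamma = 0.05)
  pop <- new_population(p, individuals = ind)
  step_days(pop, 5000, record_every = 0)
  df <- get_individuals(pop)
  expect_true(all(df$careF %in% c(10L, 20L)))
  expect_true(all(df$careM %in% c(10L, 20L)))
})

test_that("snapshots round-trip through CSV exactly", {
  p <- sim_params(seed = 15, gamma = 0.05, n0_per_sex = 80, mate_choice = TRUE)
  pop <- new_population(p)
  step_days(pop, 2500, record_every = 0)
  path <- tempfile(fileext = ".csv")
  suppressMessages(write_snapshot(pop, path))
  pop2 <- read_snapshot(path)
  a <- get_individuals(pop)
  b <- get_individuals(pop2)
  # caring individuals are restored as pre-mating; compare the rest exactly
  a$state <- NULL; b$state <- NULL
  a$days_left <- NULL; b$days_left <- NULL
  a$clutch <- NULL; b$clutch <- NULL
  rownames(a) <- rownames(b) <- NULL
  b$id <- a$id  # ids are reassigned on load
  expect_equal(a, b, tolerance = 0)
  expect_identical(pop2$params$seed, p$seed)
  unlink(c(path, paste0(path, ".json")))
})
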