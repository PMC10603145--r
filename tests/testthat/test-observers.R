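test_that("bias index and equilibrium labels behave as specified", {
  expect_gt(care_bias(17.5, 2.5), 0.5)   # strongly female-biased
  expect_lt(care_bias(2.5, 17.5), -0.5)
  expect_equal(care_bias(5, 5), 0)

  # a synthetic trajectory window with known means and unimodal histograms
  mk <- function(Tf, Tm, hf, hm) {
    s <- data.frame(care_f_mean = rep(Tf, 10), care_m_mean = rep(Tm, 10))
    list(summary = s,
         hist_f = matrix(rep(hf, each = 10), nrow = 10),
         hist_m = matrix(rep(hm, each = 10), nrow = 10))
  }
  uni <- c(rep(0, 17), 60, rep(0, 4))  # point mass at 17 days
  expect_equal(classify_equilibrium(mk(17.5, 2.5, uni, uni))$label,
               "female_biased")
  expect_equal(classify_equilibrium(mk(2.5, 17.5, uni, uni))$label,
               "male_biased")
  expect_equal(classify_equilibrium(mk(5, 5, uni, uni))$label, "egalitarian")
  bim <- c(45, rep(0, 9), 45, rep(0, 11))  # masses at 0 and 10 days
  expect_equal(classify_equilibrium(mk(10, 10, bim, uni))$label,
               "polymorphic/transition")
  # relabelling the sexes mirrors the label
  a <- classify_equilibrium(mk(16, 3, uni, uni))
  b <- classify_equilibrium(mk(3, 16, uni, uni))
  expect_equal(a$bias, -b$bias)
  expect_equal(c(a$label, b$label), c("female_biased", "male_biased"))
  expect_error(classify_equilibrium(list(summary = NULL)), "empty")
})

test_that("bimodality detector separates true modes from spread and point masses", {
  point <- c(rep(0, 18), 100, rep(0, 3))
  expect_false(detect_bimodality(point)$bimodal)
  mix <- c(45, rep(1, 9), 45, rep(0, 10))  # 45% at 0, 45% at 10, 10% spread
  out <- detect_bimodality(mix)
  expect_true(out$bimodal)
  expect_equal(out$modes, c(0, 10))
  # uniform mass has no separated peaks
  expect_false(detect_bimodality(rep(10, 21))$bimodal)
  # close-by peaks (< 5 days apart) do not count
  near <- c(rep(0, 5), 40, 0, 40, rep(0, 10))
  expect_false(detect_bimodality(near)$bimodal)
  # too little mass gives an unreliable verdict
  expect_false(detect_bimodality(c(20, 0, 0, 0, 0, 0, 20))$reliable)
})

test_that("switch detection requires persistent flanking regimes", {
  lab <- function(x) data.frame(gen = seq_along(x), label = x)
  # constant regime: no switches
  expect_equal(nrow(detect_switches(lab(rep("female_biased", 300)),
                                    persistence = 100)), 0)
  # persistent F -> transition -> persistent M: exactly one switch
  seqs <- c(rep("female_biased", 150), rep("polymorphic/transition", 5),
            rep("male_biased", 150))
  sw <- detect_switches(lab(seqs), persistence = 100)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$from, "female_biased")
  expect_equal(sw$to, "male_biased")
  # rapid alternation is filtered out entirely
  alt <- rep(c("female_biased", "male_biased"), 200)
  expect_equal(nrow(detect_switches(lab(alt), persistence = 100)), 0)
  # switch counting is invariant to the label spacing given the same
  # persistence in generations
  sparse <- data.frame(gen = seq(10, 3050, by = 10),
                       label = c(rep("female_biased", 150),
                                 rep("male_biased", 155)))
  expect_equal(nrow(detect_switches(sparse, persistence = 100)), 1)
})

test_that("daily summaries aggregate a small fixture correctly", {
  ind <- tiny_population()
  p <- deathless_params(n0_per_sex = 5)
  pop <- new_population(p, individuals = ind)
  step_days(pop, 1, record_every = 1)
  s <- sexrolesim:::collect_records(pop)$summary
  # counts partition the population (one pair mated during day 1)
  expect_equal(s$n, 5)
  expect_equal(s$n_f, 3)
  expect_equal(s$n_m, 2)
  expect_equal(s$juv_f + s$pre_f + s$search_f + s$care_f, s$n_f)
  expect_equal(s$juv_m + s$pre_m + s$search_m + s$care_m, s$n_m)
  # mean expressed care alleles match the hand computation
  expect_equal(s$care_f_mean, mean(c(10, 12, 18)))
  expect_equal(s$care_m_mean, mean(c(3, 4)))
  # the state summary agrees with the recorded aggregates
  d <- summarize_day(pop)
  expect_equal(d$care_f_mean, s$care_f_mean)
  expect_equal(d$care_m_mean, s$care_m_mean)
  expect_equal(sum(d$counts), 5)
  expect_equal(sum(d$hist_f), d$n_f)
  expect_equal(unname(d$hist_f[c("10", "12", "18")]), c(1L, 1L, 1L))
})

test_that("histogram masses sum to the per-sex population counts", {
  tr <- baseline_run()
  n <- nrow(tr$summary)
  expect_equal(rowSums(tr$hist_f), tr$summary$n_f)
  expect_equal(rowSums(tr$hist_m), tr$summary$n_m)
})

test_that("the branching-level estimator finds the plateau of a known curve", {
  # synthetic decline 20 -> 5 -> divergence, with noise
  set.seed(8)
  gen <- 1:600
  Tf <- c(seq(20, 5, length.out = 200), rep(5, 100),
          seq(5, 17.5, length.out = 300)) + rnorm(600, 0, 0.3)
  Tm <- c(seq(20, 5, length.out = 200), rep(5, 100),
          seq(5, 2.5, length.out = 300)) + rnorm(600, 0, 0.3)
  tr <- list(summary = data.frame(gen = gen, care_f_mean = Tf,
                                  care_m_mean = Tm))
  out <- branching_care_level(tr, smooth = 25)
  expect_lt(abs(out$level - 5), 0.5)
  expect_true(out$gen >= 200 && out$gen <= 320)
})
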