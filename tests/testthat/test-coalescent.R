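test_that("model and design constructors enforce their invariants", {
  expect_error(demographic_model("decline", 1000, 500), "inconsistent")
  expect_error(demographic_model("expansion", 500, 1000), "inconsistent")
  expect_error(demographic_model("constant", -5), "must be > 0")
  d <- demographic_model("decline", 500, 5000, t_change = 70)
  expect_equal(d$model_class, "decline")
  expect_error(sampling_design(c(-1, 0)), "ages")
  expect_error(mutation_model(rate = -1), "rate")
  m <- mutation_model(rate = 1.28e-8, generation_time = 20)
  expect_equal(m$rate_per_gen, 2.56e-7)
})

test_that("TMRCA respects sample ages and the two-epoch expectation", {
  demo <- demographic_model("constant", 800)
  des <- sampling_design(c(0, 300 * 20, 700 * 20))
  set.seed(91)
  tm <- replicate(300, tmrca(simulate_genealogy(des, demo)))
  expect_true(all(tm >= 700))

  # isochronous pair through a size change: piecewise-exponential integral
  N1 <- 500; N2 <- 4000; tc_gen <- 5
  demo2 <- demographic_model("decline", N1, N2, t_change = tc_gen * 20)
  des2 <- sampling_design(c(0, 0))
  set.seed(92)
  tm2 <- replicate(4000, tmrca(simulate_genealogy(des2, demo2)))
  expected <- N1 * (1 - exp(-tc_gen / N1)) + exp(-tc_gen / N1) * (tc_gen + N2)
  se <- stats::sd(tm2) / sqrt(length(tm2))
  expect_lt(abs(mean(tm2) - expected), 3 * se)
})

test_that("halving N halves the mean pair coalescence time", {
  des <- sampling_design(c(0, 0))
  set.seed(93)
  t_big <- replicate(2000, tmrca(simulate_genealogy(des, demographic_model("constant", 2000))))
  t_small <- replicate(2000, tmrca(simulate_genealogy(des, demographic_model("constant", 1000))))
  se <- sqrt(stats::var(t_big) / 4 + stats::var(t_small)) / sqrt(2000)
  expect_lt(abs(mean(t_big) / 2 - mean(t_small)), 3 * se)
})

test_that("mutation counts and transition fraction match Poisson expectations", {
  # hand-built genealogy: two tips joined at 400 generations
  gen <- structure(list(n_tips = 2L, parent = c(3L, 3L, 0L),
                        time = c(0, 0, 400), tip_ages = c(0, 0),
                        tips = data.frame(id = c("s1", "s2"),
                                          age_ybp = c(0, 0),
                                          era = c("modern", "modern"))),
                   class = "genealogy")
  mut <- mutation_model(rate = 1e-6, rate_units = "per_generation",
                        ts_tv_bias = 0.75, length = 2000L)
  set.seed(94)
  reps <- replicate(2000, {
    a <- drop_mutations(gen, mut)
    c(attr(a, "n_mutations"), attr(a, "n_transitions"))
  })
  total_blen <- 800  # two branches of 400 generations
  exp_mut <- total_blen * 1e-6 * 2000
  se_mut <- stats::sd(reps[1, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - exp_mut), 3 * se_mut)
  ts_frac <- sum(reps[2, ]) / sum(reps[1, ])
  expect_lt(abs(ts_frac - 0.75 / 1.75), 3 * sqrt(0.43 * 0.57 / sum(reps[1, ])))
})

test_that("zero mutation rate produces identical sequences", {
  des <- sampling_design(c(0, 0, 40, 40))
  demo <- demographic_model("constant", 300)
  mut <- mutation_model(rate = 0, length = 100L)
  sim <- simulate_dataset(des, demo, mut, seed = 5)
  expect_equal(length(unique(as.character(sim$alignment))), 1L)
})

test_that("simulated datasets are deterministic and follow the design", {
  des <- realize_design(builtin_design("grauer", length = 800L), seed = 9)
  demo <- demographic_model("constant", 2000)
  mut <- mutation_model(length = 800L)
  s1 <- simulate_dataset(des, demo, mut, seed = 11)
  s2 <- simulate_dataset(des, demo, mut, seed = 11)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
  expect_equal(aln_nseq(s1$alignment), 97L)
  expect_equal(sum(s1$table$era == "historical"), 68L)
  expect_equal(sum(s1$table$era == "modern"), 29L)
  expect_true(all(s1$table$age_ybp[s1$table$era == "historical"] >= 34))
  # the fast summary path agrees with full-alignment summaries
  era <- s1$table$era
  mod <- aln_subset_for_test(s1$alignment, which(era == "modern"))
  his <- aln_subset_for_test(s1$alignment, which(era == "historical"))
  full <- summarize_groups(mod, his)
  set.seed(11)
  gen <- simulate_genealogy(des, demo, generation_time = mut$generation_time)
  vs <- mitotempo:::sim_variable_sites(gen, mut)
  sparse <- mitotempo:::stats_from_tip_mat(vs$tip_mat, which(era == "modern"),
                                           which(era == "historical"), 800L)
  expect_equal(sparse, full, tolerance = 1e-12)
})
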