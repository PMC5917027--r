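make_small_table <- function(n_sims = 300, seed = 17, L = 600L) {
  des <- realize_design(builtin_design("grauer", length = L), seed = 3)
  mut <- mutation_model(ts_tv_bias = 0.933, length = L)
  build_reference_table(n_sims, des, mut, seed = seed)
}

test_that("summary statistics match hand computations", {
  A <- mt_alignment(c(m1 = "AAAA", m2 = "AAAA", m3 = "AAAA"))
  B <- mt_alignment(c(h1 = "TTTT", h2 = "TTTT", h3 = "TTTT"))
  st <- summarize_groups(A, B)
  expect_equal(unname(st), c(1, 1, 1, 1, 0, 0, 4, 1))
  st2 <- summarize_groups(A, A)
  expect_equal(unname(st2[c("P_modern", "P_historical", "fst_between")]),
               c(0, 0, 0))
  # 4 historical vs 2 modern haplotypes, one shared
  hist <- mt_alignment(c(h1 = "AAAA", h2 = "AAAT", h3 = "AATT", h4 = "ATTT"))
  mod <- mt_alignment(c(m1 = "AAAA", m2 = "CAAA"))
  st3 <- summarize_groups(mod, hist)
  expect_equal(unname(st3[c("H_modern", "H_historical", "P_modern", "P_historical")]),
               c(2, 4, 1, 3))
})

test_that("prior draws respect model order constraints and log-uniformity", {
  spec <- prior_spec()
  set.seed(101)
  for (i in 1:200) {
    d <- draw_prior("decline", spec)
    expect_gt(d$N_historical, d$N_present)
    e <- draw_prior("expansion", spec)
    expect_lt(e$N_historical, e$N_present)
    k <- draw_prior("constant", spec)
    expect_equal(k$N_present, k$N_historical)
    expect_gte(d$t_change, 30); expect_lte(d$t_change, 110)
  }
  # log of the constant-model size is uniform over the prior range
  set.seed(102)
  draws <- replicate(3000, log(draw_prior("constant", spec)$N_present))
  ks <- stats::ks.test(draws, "punif", log(100), log(1e5))
  expect_gt(ks$p.value, 0.01)
})

test_that("reference tables are balanced and worker-count invariant", {
  tab <- make_small_table(n_sims = 150, seed = 5, L = 300L)
  expect_equal(as.integer(table(tab$model)), rep(50L, 3))
  expect_true(all(is.finite(as.matrix(tab[, mitotempo:::ABC_STAT_NAMES]))))
  tab2 <- make_small_table(n_sims = 150, seed = 5, L = 300L)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  des <- realize_design(builtin_design("grauer", length = 300L), seed = 3)
  mut <- mutation_model(ts_tv_bias = 0.933, length = 300L)
  tab4 <- build_reference_table(150, des, mut, seed = 5, workers = 2L)
  expect_identical(as.data.frame(tab), as.data.frame(tab4))
})

test_that("rejection matches a brute-force sort and its edge cases", {
  tab <- make_small_table(n_sims = 300, seed = 17)
  obs <- unlist(tab[42, mitotempo:::ABC_STAT_NAMES])
  acc <- abc_reject(tab, obs, 0.01)
  expect_equal(nrow(acc), 3L)
  expect_equal(acc$.distance[1], 0)
  expect_equal(rownames(acc)[1], "42")
  # brute force: standardize by table SD and sort
  sm <- as.matrix(tab[, mitotempo:::ABC_STAT_NAMES])
  sds <- apply(sm, 2, sd); mns <- colMeans(sm)
  z <- scale(sm, center = mns, scale = sds)
  d <- sqrt(rowSums(sweep(z, 2, (obs - mns) / sds)^2))
  k <- ceiling(0.01 * nrow(tab))
  expect_equal(sort(acc$.distance), unname(sort(d)[seq_len(k)]), tolerance = 1e-9)
  # proportion 1 accepts everything
  expect_equal(nrow(abc_reject(tab, obs, 1)), nrow(tab))
  expect_error(abc_reject(tab, obs, 0), "proportion")
  # row order does not affect the accepted set of distances
  perm <- sample(nrow(tab))
  tabp <- structure(as.data.frame(tab)[perm, ],
                    class = c("abc_reference", "data.frame"),
                    stat_means = attr(tab, "stat_means"),
                    stat_sds = attr(tab, "stat_sds"))
  accp <- abc_reject(tabp, obs, 0.05)
  expect_equal(sort(accp$.distance), sort(abc_reject(tab, obs, 0.05)$.distance))
})

test_that("model posteriors sum to one at every acceptance proportion", {
  tab <- make_small_table(n_sims = 300, seed = 17)
  obs <- unlist(tab[10, mitotempo:::ABC_STAT_NAMES])
  mc <- model_posterior(tab, obs, proportions = c(0.02, 0.05, 0.1))
  sums <- tapply(mc$posterior$posterior, mc$posterior$proportion, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(nrow(mc$consistency), 3L)
  # a single-model table reports posterior 1 for that model
  one <- structure(as.data.frame(tab)[tab$model == "decline", ],
                   class = c("abc_reference", "data.frame"),
                   stat_means = attr(tab, "stat_means"),
                   stat_sds = attr(tab, "stat_sds"))
  expect_error(model_posterior(one, obs), "at least 2 models")
})

test_that("regression adjustment has the zero-slope and exact limits", {
  # zero slope: parameters independent of stats -> adjustment is a no-op
  set.seed(103)
  n <- 200
  fake <- data.frame(model = "decline",
                     N_present = exp(runif(n, log(100), log(1e4))),
                     N_historical = exp(runif(n, log(100), log(1e4))),
                     t_change = runif(n, 30, 110))
  stats_mat <- matrix(rnorm(n * 8), n)
  colnames(stats_mat) <- mitotempo:::ABC_STAT_NAMES
  fake <- cbind(fake, stats_mat)
  fake$.distance <- sqrt(rowSums(stats_mat^2))
  acc <- structure(fake, class = c("abc_accepted", "data.frame"),
                   stat_means = setNames(rep(0, 8), mitotempo:::ABC_STAT_NAMES),
                   stat_sds = setNames(rep(1, 8), mitotempo:::ABC_STAT_NAMES),
                   observed = setNames(rep(0, 8), mitotempo:::ABC_STAT_NAMES))
  adj <- regression_adjust(acc)
  # slopes are ~0, so adjusted draws stay close to the raw ones on average
  expect_lt(abs(mean(log(adj$N_present)) - mean(log(fake$N_present))), 0.25)
  expect_gt(cor(log(adj$N_present), log(fake$N_present)), 0.95)

  # exact linear relation: param = stat -> draws collapse onto the observed value
  fake2 <- fake
  fake2$N_present <- exp(stats_mat[, 1])
  fake2$N_historical <- exp(stats_mat[, 1])
  acc2 <- structure(fake2, class = c("abc_accepted", "data.frame"),
                    stat_means = attr(acc, "stat_means"),
                    stat_sds = attr(acc, "stat_sds"),
                    observed = setNames(c(0.7, rep(0, 7)), mitotempo:::ABC_STAT_NAMES))
  adj2 <- regression_adjust(acc2)
  expect_lt(max(abs(log(adj2$N_present) - 0.7)), 1e-8)

  # variance reduction under a noisy linear relation
  fake3 <- fake
  fake3$N_present <- exp(stats_mat[, 1] + rnorm(n, 0, 0.3))
  acc3 <- structure(fake3, class = c("abc_accepted", "data.frame"),
                    stat_means = attr(acc, "stat_means"),
                    stat_sds = attr(acc, "stat_sds"),
                    observed = setNames(rep(0, 8), mitotempo:::ABC_STAT_NAMES))
  adj3 <- regression_adjust(acc3)
  expect_lt(var(log(adj3$N_present)), var(log(fake3$N_present)))
})

test_that("reduction estimates follow the weighted quantile oracle", {
  post <- data.frame(N_present = rep(1, 100), N_historical = 1:100,
                     weight = rep(1, 100))
  est <- estimate_reduction(post)
  expect_equal(est$median, 50.5)
  expect_equal(est$ci95, c(3, 98))
  # all-equal sizes give ratio 1 with a degenerate interval
  post2 <- data.frame(N_present = rep(2, 10), N_historical = rep(2, 10))
  est2 <- estimate_reduction(post2)
  expect_equal(est2$median, 1)
  expect_equal(est2$ci95, c(1, 1))
})
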