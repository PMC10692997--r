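two_point_population <- function() {
  # phenotypes (0,0) and (2,2), equally frequent, via identity c
  a <- cbind(c(0, 0), c(2, 2))
  population(a, matrix(as.vector(diag(2)), 4, 2), 2)
}

test_that("total VCV matches hand computation and is translation invariant", {
  set.seed(20)
  expect_true(all(bare(total_vcv(make_fixture("uniform", N = 30))) == 0))
  m <- bare(total_vcv(two_point_population()))
  expect_equal(m, matrix(1, 2, 2)) # population denominator: var 1, cov 1
  # shifting every weight allele by a constant shifts phenotypes only
  pop <- make_fixture("fixed_c", N = 50)
  shifted <- pop; shifted$a <- shifted$a + 3
  expect_equal(bare(total_vcv(shifted)), bare(total_vcv(pop)))
  expect_error(total_vcv(population(matrix(0, 4, 1), matrix(0, 16, 1), 4)),
               "two individuals")
})

test_that("shuffling decomposes total into pleiotropy + LD exactly", {
  set.seed(21)
  pop <- make_fixture("no_ld", N = 100)
  dec <- shuffle_decompose(pop, n_shuffles = 3)
  expect_equal(bare(dec$pleiotropy) + bare(dec$ld),
               bare(dec$total))
  expect_error(shuffle_decompose(pop, n_shuffles = 0), "n_shuffles")
})

test_that("allele shuffling permutes loci without changing their content", {
  set.seed(22)
  pop <- make_fixture("no_ld", N = 40)
  shuf <- fluctG:::shuffle_population(pop)
  for (r in seq_len(nrow(pop$a)))
    expect_equal(sort(shuf$a[r, ]), sort(pop$a[r, ]))
  for (r in seq_len(nrow(pop$c)))
    expect_equal(sort(shuf$c[r, ]), sort(pop$c[r, ]))
})

test_that("perfect-coupling fixture puts covariance 0.25 entirely in LD", {
  set.seed(23)
  pop <- make_fixture("perfect_coupling", N = 500)
  tot <- bare(total_vcv(pop))
  expect_equal(tot[1, 2], 0.25)
  expect_equal(tot[1, 1], 0.25)
  dec <- shuffle_decompose(pop, n_shuffles = 100)
  draws <- vapply(dec$shuffle_draws, function(m) m[1, 2], 0)
  se <- stats::sd(draws) / sqrt(length(draws))
  # shuffled covariance is the permutation null, E = -0.25/(N-1)
  expect_lt(abs(bare(dec$pleiotropy)[1, 2] - (-0.25 / 499)), 3 * se)
  expect_lt(abs(bare(dec$ld)[1, 2] - 0.25), 3 * se + 0.25 / 499)
})

test_that("midparent regression recovers the additive map", {
  set.seed(24)
  pop <- make_fixture("fixed_c", N = 400)
  av <- additive_vcv(pop, n_pairs = 3000, n_offspring_per_pair = 10)
  expect_true(all(abs(av$h2 - 1) < 0.1))
  tot <- bare(total_vcv(pop))
  expect_true(all(abs(bare(av$sym) - tot) / abs(tot) < 0.1))
  expect_equal(bare(av$sym), (bare(av$raw) + t(bare(av$raw))) / 2)
})

test_that("zero midparent variance is reported as undefined, not zero", {
  set.seed(25)
  pop <- make_fixture("uniform", N = 50)
  av <- additive_vcv(pop, n_pairs = 100)
  expect_true(all(is.na(bare(av$raw))))
  expect_true(all(is.na(av$h2)))
})

test_that("replicate summaries time-average and preserve the identity", {
  p <- model_params(N = 50)
  rec <- run_replicate(p, environment_spec("correlated"), 50 * 200, seed = 26)
  expect_gt(length(rec$snapshots), 1)
  set.seed(26)
  s <- summarize_replicate(rec)
  expect_equal(bare(s$pleiotropy) + bare(s$ld), bare(s$total))
  # a single-snapshot record summarizes to that snapshot's matrices
  rec1 <- rec
  rec1$snapshots <- rec$snapshots[1]
  set.seed(27)
  s1 <- summarize_replicate(rec1)
  expect_equal(bare(s1$total),
               bare(total_vcv(rec$snapshots[[1]]$population)))
})

test_that("treatment comparisons behave like a Welch t-test should", {
  fake <- function(vals) lapply(vals, function(v)
    list(total = matrix(c(1, v, v, 1), 2, 2)))
  set.seed(28)
  a <- fake(rnorm(50, 1, 0.01)); b <- fake(rnorm(50, 0, 0.01))
  res <- compare_treatments(a, b, "total", "offdiag_mean")
  expect_lt(res$p_value, 1e-6)
  same <- compare_treatments(a, a, "total", "offdiag_mean")
  expect_equal(same$p_value, 1)
  expect_equal(same$ratio, 1)
  swapped <- compare_treatments(b, a, "total", "offdiag_mean")
  expect_equal(swapped$statistic, -res$statistic)
  degenerate <- fake(rep(1, 5))
  expect_error(compare_treatments(degenerate, degenerate, "total"),
               "degenerate")
})

test_that("tidy export has one row per matrix entry", {
  p <- model_params(N = 30)
  rec <- run_replicate(p, environment_spec("correlated"), 30 * 100, seed = 29)
  set.seed(29)
  tab <- vcv_tidy(list(summarize_replicate(rec)))
  expect_identical(names(tab), c("replicate", "pattern", "label",
                                 "trait_i", "trait_j", "value"))
  expect_identical(nrow(tab), 3L * 16L)
})
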