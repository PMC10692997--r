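test_that("environment specs validate their lattice and block structure", {
  expect_error(environment_spec("block_correlated"), "blocks")
  expect_error(environment_spec("block_correlated", blocks = list(1:2, 2:4)),
               "partition")
  expect_error(environment_spec("correlated", bounds = c(-1, 1),
                                step_size = 0.3), "multiple")
  sp <- environment_spec("block_correlated", blocks = list(1:2, 3:4))
  expect_length(sp$units, 2)
  expect_error(step_optimum(c(0.1, 0, 0, 0),
                            environment_spec("correlated")), "lattice")
})

test_that("correlated steps move all traits together by one step", {
  spec <- environment_spec("correlated")
  set.seed(10)
  for (i in 1:20) {
    nxt <- step_optimum(rep(0.2, 4), spec)
    expect_true(all(nxt == nxt[1]))
    expect_true(nxt[1] %in% c(0, 0.4))
  }
})

test_that("a trait at the boundary stays or moves inward, half and half", {
  spec <- environment_spec("independent", n_traits = 1)
  set.seed(11)
  nxt <- replicate(4000, step_optimum(1, spec))
  expect_true(all(nxt %in% c(1, 0.8)))
  expect_lt(abs(mean(nxt == 1) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("trajectories respect the change period and are reproducible", {
  spec <- environment_spec("independent", n_traits = 2)
  set.seed(12)
  traj <- make_trajectory(spec, 35)
  # constant within 10-generation windows, rows 1-10, 11-20, 21-30, 31-35
  for (w in list(1:10, 11:20, 21:30, 31:35))
    expect_true(all(apply(traj[w, , drop = FALSE], 2,
                          function(x) length(unique(x)) == 1)))
  spec0 <- environment_spec("correlated", step_size = 0)
  expect_true(all(make_trajectory(spec0, 50) == 0))
  set.seed(13); t1 <- make_trajectory(spec, 200)
  set.seed(13); t2 <- make_trajectory(spec, 200)
  expect_identical(t1, t2)
  expect_error(make_trajectory(spec, 10, init = c(0.05, 0)), "lattice")
})

test_that("traits stay synchronized within their stepping units", {
  set.seed(14)
  tc <- make_trajectory(environment_spec("correlated"), 500)
  expect_true(all(tc == tc[, 1]))
  tb <- make_trajectory(environment_spec("block_correlated",
                                         blocks = list(1:2, 3:4)), 500)
  expect_true(all(tb[, 1] == tb[, 2]) && all(tb[, 3] == tb[, 4]))
  expect_false(all(tb[, 2] == tb[, 3])) # blocks decouple
})

test_that("per-trait marginal step law is the same across patterns", {
  # one trait's sequence of moves {-s, 0, +s} should be indistinguishable
  # between the correlated and independent regimes
  set.seed(15)
  n <- 4000
  moves <- function(pattern) {
    spec <- environment_spec(pattern, period_generations = 1)
    tr <- make_trajectory(spec, n)
    d <- round(diff(tr[, 1]) / spec$step_size)
    tabulate(d + 2L, 3L)
  }
  tab <- rbind(moves("correlated"), moves("independent"))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("the unbounded walk leaves the [-1, 1] interval", {
  spec <- environment_spec("correlated", bounded = FALSE,
                           period_generations = 1)
  set.seed(16)
  traj <- make_trajectory(spec, 2000)
  expect_gt(max(abs(traj)), 1)
})
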