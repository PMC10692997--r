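test_that("population size is constant and no-variation runs are inert", {
  p <- model_params(N = 40, mu_a = 0, mu_c = 0)
  spec <- environment_spec("correlated")
  rec <- run_replicate(p, spec, 40 * 30, seed = 1)
  expect_identical(rec$final$N, 40L)
  expect_true(all(rec$final$a == 0) && all(rec$final$c == 0))
  # snapshot bookkeeping: last tenth of 500 generations, every 10
  p2 <- model_params(N = 100)
  rec2 <- run_replicate(p2, spec, 100 * 500, seed = 2)
  expect_identical(vapply(rec2$snapshots, `[[`, 0, "generation"),
                   c(460, 470, 480, 490, 500))
  expect_identical(rec2$final$N, 100L)
})

test_that("cached-fitness engine is bit-identical to the naive engine", {
  spec <- environment_spec("independent")
  for (sexual in c(FALSE, TRUE)) {
    p <- model_params(N = 50, mu_a = 0.01, mu_c = 0.005, sexual = sexual)
    fast <- run_replicate(p, spec, 1e4, seed = 99)
    slow <- run_replicate(p, spec, 1e4, seed = 99, naive = TRUE)
    expect_identical(fast$final$a, slow$final$a)
    expect_identical(fast$final$c, slow$final$c)
    expect_identical(fast$mean_fitness, slow$mean_fitness)
  }
})

test_that("snapshot caches agree with recomputation from the genotypes", {
  p <- model_params(N = 60)
  rec <- run_replicate(p, environment_spec("correlated"), 60 * 100, seed = 3)
  s <- rec$snapshots[[length(rec$snapshots)]]
  w <- pop_fitness(s$population, s$optimum)
  expect_true(all(w > 0 & w <= 1))
  expect_equal(dim(pop_phenotypes(s$population)), c(4, 60))
})

test_that("batches are reproducible with distinct per-replicate seeds", {
  p <- model_params(N = 30)
  spec <- environment_spec("correlated")
  b1 <- run_batch(p, spec, 2, 30 * 20, master_seed = 7)
  b2 <- run_batch(p, spec, 2, 30 * 20, master_seed = 7)
  expect_identical(b1[[1]]$final, b2[[1]]$final)
  expect_identical(b1[[2]]$final, b2[[2]]$final)
  seeds <- vapply(b1, `[[`, 0, "seed")
  expect_length(unique(seeds), 2)
  expect_false(identical(b1[[1]]$final, b1[[2]]$final))
})

test_that("a population far off the optimum still reproduces (uniform fallback)", {
  p <- model_params(N = 20)
  g <- genotype(rep(1e3, 4), diag(4)) # fitness underflows to exactly 0
  pop <- uniform_population(p, g)
  expect_identical(unname(pop_fitness(pop, rep(0, 4))), rep(0, 20))
  rec <- run_replicate(p, environment_spec("correlated"), 200, seed = 4,
                       init_pop = pop)
  expect_identical(rec$final$N, 20L)
})

test_that("with selection flattened the regimes are neutrally equivalent", {
  # enormous fitness-function variance approximates a flat landscape; the
  # per-trait genetic variance at mutation-drift balance should then not
  # depend on the optimum pattern
  v <- function(pattern, ms) {
    p <- model_params(N = 100, selection_var = 1e9)
    recs <- run_batch(p, environment_spec(pattern), 8, 100 * 300,
                      master_seed = ms)
    vapply(recs, function(r)
      mean(diag(unclass(total_vcv(r$final)))), 0)
  }
  set.seed(17)
  tt <- t.test(v("correlated", 171), v("independent", 172))
  expect_gt(tt$p.value, 0.001)
})
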