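test_that("fixing pleiotropy picks the modal allele at every c locus", {
  # 6 copies of value v, 4 of w at one locus -> everyone gets v
  a <- matrix(0, 2, 10)
  cf <- matrix(1, 4, 10)
  cf[1, ] <- c(rep(0.7, 6), rep(-0.3, 4))
  pop <- population(a, cf, 2)
  fixed <- fix_pleiotropy(pop)
  expect_true(all(fixed$c[1, ] == 0.7))
  expect_true(all(fixed$c[2:4, ] == 1))
  # already uniform -> unchanged; all columns identical afterwards
  expect_identical(fix_pleiotropy(fixed)$c, fixed$c)
  expect_true(all(fixed$c == fixed$c[, 1]))
  # tie: value carried by the lowest-indexed individual wins
  cf2 <- cf; cf2[1, ] <- c(rep(-0.3, 5), rep(0.7, 5))
  tied <- fix_pleiotropy(population(a, cf2, 2))
  expect_true(all(tied$c[1, ] == -0.3))
  # deterministic: same input, same output (the transplant copy contract)
  expect_identical(fix_pleiotropy(pop)$c, fixed$c)
})

test_that("block bookkeeping separates within- from between-block pairs", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 10
  m[3, 4] <- m[4, 3] <- 20
  m[1, 3] <- m[3, 1] <- m[1, 4] <- m[4, 1] <- 1
  m[2, 3] <- m[3, 2] <- m[2, 4] <- m[4, 2] <- 3
  bc <- block_covariance(m, list(1:2, 3:4))
  expect_equal(bc$within, 15)
  expect_equal(bc$between, 2)
})

test_that("the transplant assay returns the full grid with valid fitness", {
  design <- scale_preset("smoke")
  params <- model_params(N = design$N)
  regimes <- c("correlated", "independent")
  recs <- list()
  set.seed(40)
  for (rg in regimes)
    recs[[rg]] <- run_batch(params, environment_spec(rg), 2,
                            design$N * design$phase1_generations,
                            master_seed = sample.int(1e6, 1))
  ev <- evolvability_assay(recs, regimes, design$phase2_generations,
                           design, seed = 41)
  expect_identical(dim(ev$summary), c(2L, 2L))
  expect_true(all(ev$cells$summary > 0 & ev$cells$summary <= 1))
  expect_identical(nrow(ev$cells), 2L * 2L * 2L)
  expect_identical(names(ev$trajectories),
                   c("ancestral", "test", "replicate", "generation",
                     "mean_fitness"))
})

test_that("a smoke-scale battery emits every result schema", {
  design <- scale_preset("smoke")
  out_dir <- file.path(tempdir(), "fluctG-smoke-battery")
  battery <- run_paper_battery(design, seed = 42, out_dir = out_dir)
  expect_identical(battery$failed, 0L)
  expect_setequal(unique(battery$vcv_table$pattern),
                  c("correlated", "independent", "block_correlated"))
  expect_true(all(c("total_offdiag_mean", "pleiotropy_offdiag_mean",
                    "ld_offdiag_mean", "mutational_a_offdiag",
                    "block_total_within_vs_between",
                    "block_total_within_vs_independent",
                    "block_total_between_vs_independent") %in%
                    names(battery$tests)))
  expect_identical(dim(battery$evolvability$summary), c(3L, 3L))
  expect_true(all(file.exists(file.path(out_dir,
    c("vcv_matrices.csv", "mutational_matrices.csv",
      "fitness_trajectories.csv", "evolvability_cells.csv",
      "tests.json")))))
})
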