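#' Fix the contribution matrix at its modal values
#'
#' Sets every individual's allele at each contribution locus to the most
#' common exact value at that locus in the population (alleles arise as
#' discrete mutational lineages, so exact-value frequencies are
#' meaningful). Ties are broken in favour of the value carried by the
#' lowest-indexed individual. Weight vectors are untouched. Downstream
#' phase-2 runs should set `mu_c = 0` so pleiotropy stays frozen.
#'
#' @param pop a `population`.
#' @return the `population` with a uniform contribution matrix.
#' @export
fix_pleiotropy <- function(pop) {
  stopifnot(inherits(pop, "population"))
  modal <- function(x) {
    ux <- unique(x) # in order of first carrier, so which.max breaks ties
    ux[which.max(tabulate(match(x, ux)))] # toward the lowest-indexed one
  }
  fixed <- apply(pop$c, 1, modal)
  pop$c <- matrix(fixed, nrow(pop$c), pop$N)
  pop
}

#' Experiment design
#'
#' Scale parameters for the phase-1 (bounded, evolving pleiotropy) and
#' phase-2 (unbounded, fixed pleiotropy) stages of the transplant
#' experiment and the regime-comparison batteries. The reference design is
#' N = 1000, 4 traits / 4 weight genes, 5,000 phase-1 and 2,000 phase-2
#' generations, 500 replicates per regime; `scale_preset()` provides
#' reduced versions for desk work.
#'
#' @param N,n_traits,n_a,sexual model settings (see [model_params()]).
#' @param n_replicates replicates per regime.
#' @param phase1_generations,phase2_generations run lengths.
#' @param blocks block partition for the block-correlated regime.
#' @param n_mut_samples perturbation samples per gene class per replicate.
#' @param n_shuffles allele shuffles per snapshot.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(N = 1000, n_traits = 4, n_a = 4,
                              sexual = FALSE, n_replicates = 500,
                              phase1_generations = 5000,
                              phase2_generations = 2000,
                              blocks = list(1:2, 3:4),
                              n_mut_samples = 1e6, n_shuffles = 1) {
  structure(list(N = N, n_traits = n_traits, n_a = n_a, sexual = sexual,
                 n_replicates = n_replicates,
                 phase1_generations = phase1_generations,
                 phase2_generations = phase2_generations,
                 blocks = blocks, n_mut_samples = n_mut_samples,
                 n_shuffles = n_shuffles),
            class = "experiment_design")
}

#' Preset experiment scales
#'
#' "paper" is the full design (multi-CPU-day); "desk" is the reduced design
#' used for directional checks (N = 200, 1,000 + 500 generations, 20
#' replicates per regime); "smoke" is a seconds-long schema check.
#'
#' @param scale one of "smoke", "desk", "paper".
#' @param ... overrides passed to [experiment_design()].
#' @return an `experiment_design`.
#' @export
scale_preset <- function(scale = c("desk", "smoke", "paper"), ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    smoke = list(N = 50, n_replicates = 2, phase1_generations = 50,
                 phase2_generations = 20, n_mut_samples = 1000),
    desk = list(N = 200, n_replicates = 20, phase1_generations = 1000,
                phase2_generations = 500, n_mut_samples = 1e5),
    paper = list())
  do.call(experiment_design, modifyList(base, list(...)))
}

design_params <- function(design, mu_c = NULL) {
  p <- model_params(N = design$N, n_traits = design$n_traits,
                    n_a = design$n_a, sexual = design$sexual)
  if (!is.null(mu_c)) p$mu_c <- mu_c
  p
}

regime_spec <- function(pattern, design, bounded = TRUE) {
  environment_spec(pattern, n_traits = design$n_traits,
                   blocks = if (pattern == "block_correlated") design$blocks,
                   bounded = bounded)
}

#' Fixed-pleiotropy evolvability transplant assay
#'
#' Each phase-1 replicate population is frozen at its modal contribution
#' matrix ([fix_pleiotropy()]), copied once per test regime, and evolved
#' for `phase2_generations` with `mu_c = 0` under unbounded optima starting
#' from the zero optimum; mean fitness is recorded every 10 generations and
#' each run is summarised by its mean fitness over the last 10% of the
#' recordings.
#'
#' @param phase1_records named list: regime name -> list of `sim_record`s.
#' @param test_patterns patterns to transplant into (defaults to the
#'   ancestral regime names).
#' @param phase2_generations test-phase length in generations.
#' @param design the `experiment_design` (supplies N, gene counts, blocks).
#' @param seed seed for the phase-2 runs.
#' @return list: `cells` (data.frame ancestral, test, replicate, summary
#'   mean fitness), `trajectories` (data.frame ancestral, test, replicate,
#'   generation, mean_fitness), `summary` (3 x 3 matrix of cell means,
#'   ancestral regimes in rows).
#' @export
evolvability_assay <- function(phase1_records, test_patterns = NULL,
                               phase2_generations, design, seed) {
  stopifnot(length(phase1_records) >= 1)
  test_patterns <- test_patterns %||% names(phase1_records)
  params2 <- design_params(design, mu_c = 0) # pleiotropy frozen
  n_events <- phase2_generations * params2$N
  set.seed(seed)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1L,
               length(phase1_records) * length(test_patterns) *
                 max(lengths(phase1_records))),
    nrow = max(lengths(phase1_records)))
  cells <- list(); trajs <- list()
  col <- 0L
  for (anc in names(phase1_records)) {
    for (test in test_patterns) {
      col <- col + 1L
      spec <- regime_spec(test, design, bounded = FALSE)
      for (r in seq_along(phase1_records[[anc]])) {
        # each of the three copies starts from the same frozen population
        start <- fix_pleiotropy(phase1_records[[anc]][[r]]$final)
        rec <- run_replicate(params2, spec, n_events,
                             seed = seeds[r, col], snapshot_every = 0,
                             snapshot_fraction = 0, fitness_every = 10,
                             init_pop = start, replicate_id = r)
        mf <- rec$mean_fitness
        last <- mf[mf$generation > 0.9 * phase2_generations, , drop = FALSE]
        cells[[length(cells) + 1L]] <- data.frame(
          ancestral = anc, test = test, replicate = r,
          summary = mean(last$mean_fitness))
        trajs[[length(trajs) + 1L]] <- cbind(
          ancestral = anc, test = test, replicate = r, mf)
      }
    }
  }
  cells <- do.call(rbind, cells)
  summary <- tapply(cells$summary, list(cells$ancestral, cells$test), mean)
  list(cells = cells, trajectories = do.call(rbind, trajs),
       summary = summary)
}

block_pairs <- function(blocks, n_traits) {
  within <- matrix(FALSE, n_traits, n_traits)
  for (b in blocks) within[b, b] <- TRUE
  diag(within) <- FALSE
  between <- !within & row(within) != col(within)
  list(within = which(within), between = which(between))
}

#' Mean covariance within and between trait blocks
#' @param m a traits x traits matrix.
#' @param blocks list of trait-index vectors.
#' @return list with `within` and `between` mean off-diagonal covariance.
#' @export
block_covariance <- function(m, blocks) {
  m <- unclass(m)
  bp <- block_pairs(blocks, nrow(m))
  list(within = mean(m[bp$within]), between = mean(m[bp$between]))
}

#' Run the full experiment battery
#'
#' Orchestrates the study grid at a configurable scale: phase-1 batches in
#' each requested regime, per-replicate (co)variance summaries and
#' pleiotropy/LD decompositions, mutational moments per gene class, the
#' regime comparisons (correlated vs independent; within-block vs
#' between-block vs independent), and optionally the 3x3 evolvability
#' transplant. Replicates that fail are dropped with a recorded count,
#' never imputed.
#'
#' @param design an `experiment_design` (see [scale_preset()]).
#' @param seed master seed.
#' @param regimes which phase-1 regimes to run.
#' @param evolvability run the transplant assay?
#' @param mutational estimate mutational moments?
#' @param out_dir optional directory for tidy CSV / JSON output.
#' @return list with `summaries` (per regime), `mutational`, `tests`,
#'   `evolvability`, `failed` (count), and the tidy tables.
#' @export
run_paper_battery <- function(design, seed,
                              regimes = c("correlated", "independent",
                                          "block_correlated"),
                              evolvability = TRUE, mutational = TRUE,
                              out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  params <- design_params(design)
  n_events <- design$phase1_generations * params$N
  set.seed(seed)
  batch_seeds <- setNames(sample.int(.Machine$integer.max - 1L,
                                     length(regimes) + 2L)[seq_along(regimes)],
                          regimes)
  analysis_seed <- sample.int(.Machine$integer.max - 1L, 1)
  evolv_seed <- sample.int(.Machine$integer.max - 1L, 1)

  records <- list(); summaries <- list(); mut <- list(); failed <- 0L
  for (rg in regimes) {
    spec <- regime_spec(rg, design)
    recs <- run_batch(params, spec, design$n_replicates, n_events,
                      master_seed = batch_seeds[[rg]])
    records[[rg]] <- recs
  }
  set.seed(analysis_seed)
  for (rg in regimes) {
    sums <- list(); muts <- list()
    for (rec in records[[rg]]) {
      res <- tryCatch({
        s <- summarize_replicate(rec, n_shuffles = design$n_shuffles,
                                 additive = design$sexual)
        m <- NULL
        if (mutational) {
          ma <- sample_mutational_moments(rec, "a", design$n_mut_samples)
          mc <- sample_mutational_moments(rec, "c", design$n_mut_samples)
          m <- list(a = ma, c = mc,
                    total = total_mutational_matrix(ma, mc, params))
          m$a$z <- m$a$dz <- m$c$z <- m$c$dz <- NULL # drop bulky draws
        }
        list(s = s, m = m)
      }, error = function(e) {
        warning("replicate ", rec$replicate_id, " (", rg, ") failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) { failed <- failed + 1L; next }
      sums[[length(sums) + 1L]] <- res$s
      if (mutational) muts[[length(muts) + 1L]] <- res$m
    }
    summaries[[rg]] <- sums
    if (mutational) mut[[rg]] <- muts
  }

  # degenerate groups are reported as failures, never as fabricated p-values
  safely <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  tests <- list()
  if (all(c("correlated", "independent") %in% regimes)) {
    co <- summaries$correlated; ind <- summaries$independent
    for (lb in c("total", "pleiotropy", "ld"))
      for (sel in c("offdiag_mean", "diag_mean"))
        tests[[paste(lb, sel, sep = "_")]] <-
          safely(compare_treatments(co, ind, lb, sel))
    if (mutational) {
      amc <- function(ms) vapply(ms, function(m)
        vcv_entry(m$a$M_star, "offdiag_mean"), 0)
      tests$mutational_a_offdiag <- safely({
        tt <- t.test(amc(mut$correlated), amc(mut$independent))
        list(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, mean_A = mean(amc(mut$correlated)),
             mean_B = mean(amc(mut$independent)))
      })
    }
  }
  if ("block_correlated" %in% regimes) {
    bsum <- summaries$block_correlated
    for (lb in c("total", "pleiotropy", "ld")) {
      wi <- vapply(bsum, function(s)
        block_covariance(s[[lb]], design$blocks)$within, 0)
      be <- vapply(bsum, function(s)
        block_covariance(s[[lb]], design$blocks)$between, 0)
      tests[[paste0("block_", lb, "_within_vs_between")]] <- safely({
        tt <- t.test(wi, be, paired = TRUE) # same replicates supply both
        list(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, mean_A = mean(wi), mean_B = mean(be),
             ratio = mean(wi) / mean(be), values_A = wi, values_B = be)
      })
      if ("independent" %in% regimes) {
        io <- vapply(summaries$independent, function(s)
          vcv_entry(s[[lb]], "offdiag_mean"), 0)
        tests[[paste0("block_", lb, "_within_vs_independent")]] <- safely({
          tw <- t.test(wi, io)
          list(statistic = unname(tw$statistic), df = unname(tw$parameter),
               p_value = tw$p.value, mean_A = mean(wi), mean_B = mean(io),
               ratio = mean(wi) / mean(io))
        })
        tests[[paste0("block_", lb, "_between_vs_independent")]] <- safely({
          tb <- t.test(be, io)
          list(statistic = unname(tb$statistic), df = unname(tb$parameter),
               p_value = tb$p.value, mean_A = mean(be), mean_B = mean(io),
               ratio = mean(be) / mean(io))
        })
      }
    }
  }

  evolv <- NULL
  if (evolvability)
    evolv <- evolvability_assay(records, regimes,
                                design$phase2_generations, design,
                                seed = evolv_seed)

  out <- list(design = design, seed = seed, summaries = summaries,
              mutational = if (mutational) mut, tests = tests,
              evolvability = evolv, failed = failed,
              vcv_table = vcv_tidy(do.call(c, unname(summaries))))
  if (!is.null(out_dir)) write_battery(out, out_dir)
  out
}

write_battery <- function(battery, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(battery$vcv_table, file.path(out_dir, "vcv_matrices.csv"),
            row.names = FALSE)
  if (!is.null(battery$mutational)) {
    mt <- do.call(rbind, lapply(names(battery$mutational), function(rg)
      mutational_tidy(battery$mutational[[rg]], rg)))
    write.csv(mt, file.path(out_dir, "mutational_matrices.csv"),
              row.names = FALSE)
  }
  if (!is.null(battery$evolvability)) {
    write.csv(battery$evolvability$trajectories,
              file.path(out_dir, "fitness_trajectories.csv"),
              row.names = FALSE)
    write.csv(battery$evolvability$cells,
              file.path(out_dir, "evolvability_cells.csv"),
              row.names = FALSE)
  }
  slim <- lapply(battery$tests, function(t)
    t[setdiff(names(t), c("values_A", "values_B"))])
  jsonlite::write_json(slim, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
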