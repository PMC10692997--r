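#' Run one Moran replicate
#'
#' Simulates `n_events` birth--death events: each event draws a parent (two
#' parents under sexual reproduction, combined by free recombination) with
#' probability proportional to fitness, mutates the offspring, and replaces
#' a uniformly chosen individual, holding N constant. A generation is N
#' events; the optimum trajectory is pre-drawn and advanced on schedule,
#' with all fitnesses refreshed whenever the optimum moves. Full-population
#' snapshots are recorded in the final `snapshot_fraction` of the run every
#' `snapshot_every` generations (with the defaults and a 5,000-generation
#' run this yields 50 snapshots). If every fitness underflows to zero the
#' parent is drawn uniformly.
#'
#' The run is bit-for-bit reproducible at a fixed `seed`: the trajectory is
#' drawn first from the seeded stream, then the event loop consumes the
#' remainder.
#'
#' @param params a `model_params`.
#' @param spec an `environment_spec`.
#' @param n_events number of birth--death events.
#' @param seed integer seed for this replicate.
#' @param snapshot_every snapshot cadence in generations.
#' @param snapshot_fraction final fraction of the run in which snapshots are
#'   taken.
#' @param fitness_every cadence (generations) of mean-fitness recording; 0
#'   disables it.
#' @param init_pop optional starting `population` (defaults to genetically
#'   uniform at the origin).
#' @param trajectory optional pre-drawn `optimum_trajectory`.
#' @param init_opt initial optimum when the trajectory is drawn here.
#' @param naive use the reference engine that recomputes every fitness at
#'   every event instead of caching (identical output, much slower; kept as
#'   a verification oracle).
#' @param replicate_id identifier stored in the record.
#' @return an object of class `sim_record`: params, spec, seed, snapshots
#'   (each with generation, population, optimum), the final population, and
#'   the mean-fitness series.
#' @export
run_replicate <- function(params, spec, n_events, seed,
                          snapshot_every = 10, snapshot_fraction = 0.1,
                          fitness_every = 10, init_pop = NULL,
                          trajectory = NULL, init_opt = NULL,
                          naive = FALSE, replicate_id = 1L) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "environment_spec"),
            n_events >= 1)
  if (spec$n_traits != params$n_traits)
    stop("environment and model disagree on the number of traits")
  set.seed(seed)
  n_gen <- ceiling(n_events / params$N)
  if (is.null(trajectory))
    trajectory <- make_trajectory(spec, n_gen, init = init_opt)
  if (nrow(trajectory) < n_gen)
    stop("trajectory covers ", nrow(trajectory), " generations, need ", n_gen)
  pop <- init_pop %||% uniform_population(params)
  stopifnot(pop$N == params$N, pop$n_traits == params$n_traits,
            pop$n_a == params$n_a)

  full_gens <- floor(n_events / params$N)
  snap_gens <- integer(0)
  if (snapshot_every > 0 && snapshot_fraction > 0) {
    cand <- seq_len(full_gens)
    snap_gens <- cand[cand > (1 - snapshot_fraction) * full_gens &
                        cand %% snapshot_every == 0]
  }

  res <- .moran_engine_cpp(pop$a, pop$c, unclass(trajectory),
                           as.double(n_events), params$mu_a, params$mu_c,
                           params$mut_var, params$selection_var,
                           params$sexual, as.integer(snap_gens),
                           as.integer(fitness_every), naive)

  snapshots <- lapply(res$snapshots, function(s)
    list(generation = s$generation,
         population = population(s$a, s$c, params$n_traits),
         optimum = as.numeric(s$optimum)))
  structure(list(replicate_id = replicate_id, seed = seed, params = params,
                 spec = spec, n_events = n_events,
                 snapshots = snapshots,
                 final = population(res$a, res$c, params$n_traits),
                 final_optimum = trajectory[n_gen, ],
                 mean_fitness = data.frame(
                   generation = res$fitness_generation,
                   mean_fitness = res$mean_fitness)),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("Moran simulation record: replicate", x$replicate_id,
      "| N =", x$params$N, "|", format(x$n_events, big.mark = ","),
      "events |", length(x$snapshots), "snapshots |",
      x$spec$pattern, "optima\n")
  invisible(x)
}

#' Run a batch of independent replicates
#'
#' Sub-seeds are drawn once from `master_seed`, so the batch is reproducible
#' and each replicate is independent of the execution order.
#'
#' @param params,spec,n_events as in [run_replicate()].
#' @param n_replicates number of replicates.
#' @param master_seed master seed for the batch.
#' @param ... passed to [run_replicate()].
#' @return list of `sim_record`s.
#' @export
run_batch <- function(params, spec, n_replicates, n_events, master_seed, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(master_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  lapply(seq_len(n_replicates), function(r)
    run_replicate(params, spec, n_events, seed = sub_seeds[r],
                  replicate_id = r, ...))
}
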