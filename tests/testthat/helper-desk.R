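# Shared reduced-scale simulation battery (N = 200, 1,000 generations,
# 20 replicates per regime), computed once per test run and cached; the
# acceptance tests for the regime comparisons, modularity, and the
# evolvability transplant all read from this cache.

desk_cache <- new.env(parent = emptyenv())

desk_runs <- function() {
  if (!is.null(desk_cache$runs)) return(desk_cache$runs)
  params <- model_params(N = 200)
  design <- scale_preset("desk")
  blocks <- list(1:2, 3:4)
  n_events <- 200 * 1000
  set.seed(42)
  seeds <- sample.int(.Machine$integer.max - 1L, 5)
  records <- list(
    correlated = run_batch(params, environment_spec("correlated"),
                           20, n_events, master_seed = seeds[1]),
    independent = run_batch(params, environment_spec("independent"),
                            20, n_events, master_seed = seeds[2]),
    block_correlated = run_batch(
      params, environment_spec("block_correlated", blocks = blocks),
      20, n_events, master_seed = seeds[3]))
  set.seed(seeds[4])
  summaries <- lapply(records, function(rs) lapply(rs, summarize_replicate))
  desk_cache$runs <- list(records = records, summaries = summaries,
                          params = params, design = design, blocks = blocks,
                          evolv_seed = seeds[5])
  desk_cache$runs
}

# chunked moment estimates -> mean and Monte-Carlo standard error per entry
chunked_mstar <- function(pop, gene_class, n_chunks, chunk_size) {
  draws <- lapply(seq_len(n_chunks), function(i)
    sample_mutational_moments(pop, gene_class, chunk_size)$M_star)
  arr <- simplify2array(draws)
  list(mean = apply(arr, 1:2, mean),
       se = apply(arr, 1:2, stats::sd) / sqrt(n_chunks))
}

# strip vcv_matrix class/label attributes for numeric comparison
bare <- function(m) array(as.numeric(m), dim = dim(m))
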