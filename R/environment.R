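#' Specification of a fluctuating-optimum environment
#'
#' Optima move on a step lattice: every `period_generations` generations each
#' stepping unit draws +/- `step_size` with probability 1/2. In the
#' `correlated` pattern all traits form one unit (they move in synchrony),
#' in `independent` every trait is its own unit, and in `block_correlated`
#' the units are the supplied blocks (correlated within, independent
#' between). In bounded mode a proposed step that would leave `bounds` is
#' cancelled for that trait, so a trait sitting at a boundary stays with
#' probability 1/2 and moves one step inward with probability 1/2 — the
#' reflecting rule that makes the stationary distribution uniform over the
#' lattice.
#'
#' @param pattern "correlated", "independent", or "block_correlated".
#' @param n_traits number of traits.
#' @param blocks for `block_correlated`, a list of integer vectors
#'   partitioning `1:n_traits`.
#' @param step_size magnitude of one optimum step.
#' @param period_generations generations between environment changes.
#' @param bounded logical; confine optima to `bounds`?
#' @param bounds length-2 numeric, lower < upper; the width must be an
#'   integer multiple of `step_size` so the lattice is well defined.
#' @return an object of class `environment_spec`.
#' @export
environment_spec <- function(pattern = c("correlated", "independent",
                                         "block_correlated"),
                             n_traits = 4, blocks = NULL, step_size = 0.2,
                             period_generations = 10, bounded = TRUE,
                             bounds = c(-1, 1)) {
  pattern <- match.arg(pattern)
  stopifnot(step_size >= 0, period_generations >= 1, length(bounds) == 2,
            bounds[1] < bounds[2])
  if (bounded && step_size > 0) {
    k <- (bounds[2] - bounds[1]) / step_size
    if (abs(k - round(k)) > 1e-9)
      stop("bounds width is not an integer multiple of step_size")
  }
  units <- switch(pattern,
    correlated = list(seq_len(n_traits)),
    independent = as.list(seq_len(n_traits)),
    block_correlated = {
      if (is.null(blocks)) stop("block_correlated pattern requires blocks")
      idx <- sort(unlist(blocks))
      if (!identical(idx, seq_len(n_traits)))
        stop("blocks must partition 1:n_traits exactly")
      lapply(blocks, as.integer)
    })
  structure(list(pattern = pattern, n_traits = as.integer(n_traits),
                 blocks = if (pattern == "block_correlated") units else NULL,
                 units = units, step_size = step_size,
                 period_generations = as.integer(period_generations),
                 bounded = isTRUE(bounded), bounds = as.numeric(bounds)),
            class = "environment_spec")
}

on_lattice <- function(x, spec, tol = 1e-8) {
  if (!spec$bounded || spec$step_size == 0) return(TRUE)
  if (any(x < spec$bounds[1] - tol | x > spec$bounds[2] + tol)) return(FALSE)
  k <- (x - spec$bounds[1]) / spec$step_size
  all(abs(k - round(k)) <= tol)
}

#' Advance the optimum by one environmental change
#'
#' Draws one +/- step per stepping unit (see [environment_spec()]) and
#' applies it to every trait in the unit; in bounded mode a trait whose
#' proposed position would leave the bounds keeps its current position
#' instead.
#'
#' @param opt current optimum vector.
#' @param spec an `environment_spec`.
#' @param validate check that `opt` lies on the bounded lattice (disable in
#'   tight loops once validated).
#' @return the next optimum vector.
#' @export
step_optimum <- function(opt, spec, validate = TRUE) {
  if (validate) {
    if (length(opt) != spec$n_traits)
      stop("optimum has length ", length(opt), ", expected ", spec$n_traits)
    if (!on_lattice(opt, spec))
      stop("optimum is off the bounded step lattice")
  }
  if (spec$step_size == 0) return(opt)
  for (u in spec$units) {
    d <- if (runif(1) < 0.5) spec$step_size else -spec$step_size
    prop <- opt[u] + d
    if (spec$bounded) {
      bad <- prop < spec$bounds[1] - 1e-9 | prop > spec$bounds[2] + 1e-9
      prop[bad] <- opt[u][bad]
    }
    opt[u] <- prop
  }
  opt
}

#' Pre-draw a full optimum trajectory
#'
#' One row per generation (row g is the optimum in force during generation
#' g, 1-based); the optimum changes only at generations
#' `1 + k * period_generations`. Pre-drawing the whole sequence lets the
#' simulator and downstream analyses see identical environments.
#'
#' @param spec an `environment_spec`.
#' @param n_generations number of generations to cover.
#' @param init initial optimum (defaults to the zero vector, the lattice
#'   centre).
#' @return numeric matrix `n_generations` x `n_traits` of class
#'   `optimum_trajectory`.
#' @export
make_trajectory <- function(spec, n_generations, init = NULL) {
  stopifnot(n_generations >= 1)
  init <- init %||% rep(0, spec$n_traits)
  if (!on_lattice(init, spec))
    stop("initial optimum is off the bounded step lattice")
  traj <- matrix(NA_real_, n_generations, spec$n_traits)
  opt <- as.numeric(init)
  for (g in seq_len(n_generations)) {
    if (g > 1 && (g - 1) %% spec$period_generations == 0)
      opt <- step_optimum(opt, spec, validate = FALSE)
    traj[g, ] <- opt
  }
  class(traj) <- c("optimum_trajectory", class(traj))
  traj
}

#' Exact transition matrix of the one-trait bounded optimum walk
#'
#' States are the lattice points from `bounds[1]` to `bounds[2]` in steps of
#' `step_size`. Interior states move one step either way with probability
#' 1/2; boundary states stay with probability 1/2 and move inward with
#' probability 1/2. The matrix is doubly stochastic, so its stationary
#' distribution is uniform over the lattice.
#'
#' @param spec an `environment_spec` (only step_size/bounds are used).
#' @return list with `states` (lattice points) and `P` (transition matrix).
#' @export
walk_transition_matrix <- function(spec = environment_spec("independent",
                                                           n_traits = 1)) {
  states <- seq(spec$bounds[1], spec$bounds[2], by = spec$step_size)
  n <- length(states)
  P <- matrix(0, n, n)
  for (s in seq_len(n)) {
    up <- min(s + 1, n); down <- max(s - 1, 1)
    P[s, up] <- P[s, up] + 0.5   # stays in place when up == s (boundary)
    P[s, down] <- P[s, down] + 0.5
  }
  list(states = states, P = P)
}

#' Export a trajectory as a tidy CSV
#' @param traj an `optimum_trajectory`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  df <- data.frame(generation = seq_len(nrow(traj)), unclass(traj))
  names(df) <- c("generation", paste0("trait_", seq_len(ncol(traj))))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
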