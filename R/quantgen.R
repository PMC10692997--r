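vcv_matrix <- function(m, label, provenance = NULL) {
  structure(m, label = label, provenance = provenance,
            class = c("vcv_matrix", class(m)))
}

#' @export
print.vcv_matrix <- function(x, ...) {
  cat("VCV matrix [", attr(x, "label"), "]\n", sep = "")
  print(unclass(`attributes<-`(x, list(dim = dim(x)))), ...)
  invisible(x)
}

#' Total genetic variance--covariance matrix of a population
#'
#' The covariance across individuals of the trait values, with the
#' population denominator 1/N. The model has no environmental noise, so the
#' phenotypic matrix is the total genetic matrix.
#'
#' @param pop a `population` with at least two individuals.
#' @return a `vcv_matrix` labelled "total" (`n_traits` x `n_traits`).
#' @export
total_vcv <- function(pop) {
  stopifnot(inherits(pop, "population"))
  if (pop$N < 2) stop("need at least two individuals for a covariance")
  z <- pop_phenotypes(pop)
  zc <- z - rowMeans(z)
  vcv_matrix(tcrossprod(zc) / pop$N, "total")
}

shuffle_population <- function(pop) {
  a <- pop$a; cf <- pop$c
  for (r in seq_len(nrow(a))) a[r, ] <- a[r, sample.int(pop$N)]
  for (r in seq_len(nrow(cf))) cf[r, ] <- cf[r, sample.int(pop$N)]
  population(a, cf, pop$n_traits)
}

#' Decompose total (co)variance into pleiotropy and linkage disequilibrium
#'
#' Permutes the alleles at every locus (each weight gene and each
#' contribution gene independently) among individuals, which destroys
#' linkage disequilibrium while leaving the allele content of every locus
#' untouched; the (co)variance of the shuffled population is therefore due
#' to pleiotropy alone. The LD component is the total matrix minus the
#' pleiotropy matrix, so the decomposition is exact by construction. One
#' shuffle is the default; averaging several lowers the Monte-Carlo noise
#' of the pleiotropy estimate.
#'
#' @param pop a `population`.
#' @param n_shuffles number of independent shuffles to average.
#' @return list with `pleiotropy` and `ld` matrices (`vcv_matrix`), the
#'   `total` matrix, and `shuffle_draws` (list of the per-shuffle matrices).
#' @export
shuffle_decompose <- function(pop, n_shuffles = 1) {
  stopifnot(inherits(pop, "population"), n_shuffles >= 1)
  tot <- total_vcv(pop)
  draws <- lapply(seq_len(n_shuffles),
                  function(i) unclass(total_vcv(shuffle_population(pop))))
  pleio <- Reduce(`+`, draws) / n_shuffles
  list(pleiotropy = vcv_matrix(pleio, "pleiotropy"),
       ld = vcv_matrix(unclass(tot) - pleio, "LD"),
       total = tot, shuffle_draws = draws)
}

#' Additive genetic (co)variance by midparent--offspring regression
#'
#' Random couples are drawn uniformly with replacement; each couple's
#' offspring are produced by free recombination (no mutation) and averaged.
#' Heritability of trait i is the OLS slope of mean-offspring trait i on
#' midparent trait i, and the additive variance is that slope times the
#' phenotypic variance of trait i in the population. The additive
#' covariance (i, j) is the slope of mean-offspring trait j on midparent
#' trait i times the phenotypic variance of trait i; this estimator is not
#' symmetric in (i, j), so the raw matrix is returned alongside its
#' symmetrised average. A trait with zero midparent variance yields NA
#' entries (undefined, not zero).
#'
#' @param pop a sexual-model `population`.
#' @param n_pairs number of random couples (default 1000).
#' @param n_offspring_per_pair offspring per couple to average over.
#' @return list with `raw` (asymmetric `vcv_matrix` "additive"), `sym`
#'   (symmetrised), `h2` (per-trait heritability slopes), `n_pairs`.
#' @export
additive_vcv <- function(pop, n_pairs = 1000, n_offspring_per_pair = 10) {
  stopifnot(inherits(pop, "population"), n_pairs >= 2,
            n_offspring_per_pair >= 1)
  nt <- pop$n_traits
  p1 <- sample.int(pop$N, n_pairs, replace = TRUE)
  p2 <- sample.int(pop$N, n_pairs, replace = TRUE)
  z <- pop_phenotypes(pop)
  mid <- (z[, p1, drop = FALSE] + z[, p2, drop = FALSE]) / 2

  off_sum <- matrix(0, nt, n_pairs)
  na <- pop$n_a; nc <- nrow(pop$c)
  a1 <- pop$a[, p1, drop = FALSE]; a2 <- pop$a[, p2, drop = FALSE]
  c1 <- pop$c[, p1, drop = FALSE]; c2 <- pop$c[, p2, drop = FALSE]
  for (k in seq_len(n_offspring_per_pair)) {
    pick_a <- matrix(runif(na * n_pairs) < 0.5, na, n_pairs)
    pick_c <- matrix(runif(nc * n_pairs) < 0.5, nc, n_pairs)
    ao <- ifelse(pick_a, a1, a2)
    co <- ifelse(pick_c, c1, c2)
    off_sum <- off_sum + pop_phenotypes(population(ao, co, nt))
  }
  off <- off_sum / n_offspring_per_pair

  vz <- apply(z, 1, function(x) mean((x - mean(x))^2)) # population variance
  vmid <- apply(mid, 1, var)
  raw <- matrix(NA_real_, nt, nt)
  h2 <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    if (vmid[i] <= 0) next # undefined: left NA
    for (j in seq_len(nt)) {
      slope <- cov(mid[i, ], off[j, ]) / var(mid[i, ])
      raw[i, j] <- slope * vz[i]
    }
    h2[i] <- cov(mid[i, ], off[i, ]) / var(mid[i, ]) # slope = heritability
  }
  list(raw = vcv_matrix(raw, "additive"),
       sym = vcv_matrix((raw + t(raw)) / 2, "additive"),
       h2 = h2, n_pairs = n_pairs)
}

#' Time-averaged (co)variance matrices of one replicate
#'
#' Applies [total_vcv()], [shuffle_decompose()] and (for sexual models,
#' optionally) [additive_vcv()] to every recorded snapshot and averages
#' each matrix elementwise over snapshots. Averaging is linear, so the
#' pleiotropy + LD = total identity is preserved.
#'
#' @param record a `sim_record` with at least one snapshot.
#' @param n_shuffles shuffles per snapshot for the decomposition.
#' @param additive compute the additive matrix (sexual populations)?
#' @param n_pairs,n_offspring_per_pair passed to [additive_vcv()].
#' @param keep_snapshots retain the per-snapshot matrices?
#' @return an object of class `replicate_summary`: time-averaged matrices
#'   under `$total`, `$pleiotropy`, `$ld` (and `$additive`, `$h2` if
#'   requested), plus the mean-fitness series.
#' @export
summarize_replicate <- function(record, n_shuffles = 1, additive = FALSE,
                                n_pairs = 1000, n_offspring_per_pair = 10,
                                keep_snapshots = FALSE) {
  stopifnot(inherits(record, "sim_record"))
  if (length(record$snapshots) < 1) stop("record has no snapshots")
  per <- lapply(record$snapshots, function(s) {
    dec <- shuffle_decompose(s$population, n_shuffles)
    out <- list(total = unclass(dec$total),
                pleiotropy = unclass(dec$pleiotropy),
                ld = unclass(dec$ld))
    if (additive) {
      av <- additive_vcv(s$population, n_pairs, n_offspring_per_pair)
      out$additive <- unclass(av$sym)
      out$additive_raw <- unclass(av$raw)
      out$h2 <- av$h2
    }
    out
  })
  avg <- function(name) {
    Reduce(`+`, lapply(per, `[[`, name)) / length(per)
  }
  out <- list(replicate_id = record$replicate_id,
              pattern = record$spec$pattern,
              n_snapshots = length(per),
              total = vcv_matrix(avg("total"), "total", "time-averaged"),
              pleiotropy = vcv_matrix(avg("pleiotropy"), "pleiotropy",
                                      "time-averaged"),
              ld = vcv_matrix(avg("ld"), "LD", "time-averaged"),
              mean_fitness = record$mean_fitness)
  if (additive) {
    out$additive <- vcv_matrix(avg("additive"), "additive", "time-averaged")
    out$additive_raw <- vcv_matrix(avg("additive_raw"), "additive",
                                   "time-averaged")
    out$h2 <- Reduce(`+`, lapply(per, `[[`, "h2")) / length(per)
  }
  if (keep_snapshots) out$per_snapshot <- per
  structure(out, class = "replicate_summary")
}

#' Scalar summaries of a VCV matrix
#'
#' `selector` picks the quantity compared across replicates: the mean of
#' the off-diagonal entries, the mean of the diagonal, or one entry (i, j).
#'
#' @param m a matrix.
#' @param selector "offdiag_mean", "diag_mean", or an integer pair c(i, j).
#' @return a scalar.
#' @export
vcv_entry <- function(m, selector = "offdiag_mean") {
  m <- unclass(m)
  if (is.numeric(selector) && length(selector) == 2)
    return(m[selector[1], selector[2]])
  switch(match.arg(selector, c("offdiag_mean", "diag_mean")),
         offdiag_mean = mean(m[row(m) != col(m)]),
         diag_mean = mean(diag(m)))
}

#' Compare a matrix entry between two treatment groups
#'
#' Extracts one scalar per replicate summary (via [vcv_entry()] on the
#' matrix named by `label`) and runs a Welch two-sample t-test across
#' groups, reporting the statistic, degrees of freedom, p-value, group
#' means, and the ratio of group means (A / B).
#'
#' @param groupA,groupB lists of `replicate_summary` objects (>= 2 each).
#' @param label which matrix: "total", "pleiotropy", "ld", or "additive".
#' @param selector passed to [vcv_entry()].
#' @param alternative as in [t.test()] ("two.sided", "greater", "less",
#'   with respect to A minus B).
#' @return list: `statistic`, `df`, `p_value`, `mean_A`, `mean_B`, `ratio`,
#'   `values_A`, `values_B`.
#' @export
compare_treatments <- function(groupA, groupB, label = "total",
                               selector = "offdiag_mean",
                               alternative = "two.sided") {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  xa <- vapply(groupA, function(s) vcv_entry(s[[label]], selector), 0)
  xb <- vapply(groupB, function(s) vcv_entry(s[[label]], selector), 0)
  if (var(xa) == 0 && var(xb) == 0)
    stop("both groups are degenerate (zero variance); no test performed")
  tt <- t.test(xa, xb, alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_A = mean(xa), mean_B = mean(xb),
       ratio = mean(xa) / mean(xb), values_A = xa, values_B = xb)
}

#' Tidy long-format table of summary matrices
#'
#' @param summaries list of `replicate_summary` objects.
#' @param labels which matrices to include.
#' @return data.frame with columns replicate, pattern, label, trait_i,
#'   trait_j, value.
#' @export
vcv_tidy <- function(summaries,
                     labels = c("total", "pleiotropy", "ld")) {
  rows <- list()
  for (s in summaries) for (lb in labels) {
    m <- s[[lb]]
    if (is.null(m)) next
    nt <- nrow(m)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = s$replicate_id, pattern = s$pattern, label = lb,
      trait_i = rep(seq_len(nt), nt), trait_j = rep(seq_len(nt), each = nt),
      value = as.vector(unclass(m)))
  }
  do.call(rbind, rows)
}
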