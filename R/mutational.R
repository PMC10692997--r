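#' Mutational (co)variance moments by single-mutation perturbation
#'
#' Estimates the per-single-mutation change in the trait (co)variance
#' matrix, M*, for one gene class. Each sample draws an individual
#' uniformly (with replacement, pooling all snapshots of the record), draws
#' one gene uniformly within the class ("a" = weight genes, "c" =
#' contribution genes), perturbs that allele by a Normal(0, `mut_var`)
#' draw, and records the phenotype before (z) and the change (dz). Then
#'
#'   M*_ii = Var(dz_i) + 2 Cov(dz_i, z_i)
#'   M*_ij = Cov(dz_i, dz_j) + Cov(z_i, dz_j) + Cov(dz_i, z_j)
#'
#' with all moments taken over the samples (plain sample covariances); the
#' matrix is symmetric by construction. Sampled individuals are never
#' modified.
#'
#' @param record a `sim_record` with snapshots, or a single `population`.
#' @param gene_class "a" or "c".
#' @param n_samples number of perturbation samples (>= 2).
#' @param mut_var mutational-effect variance; defaults to the record's
#'   params (0.5 for a bare population).
#' @return object of class `mutational_moments`: `M_star`, `gene_class`,
#'   `n_samples`, and the per-sample matrices `z`, `dz` (traits x samples)
#'   for moment-level diagnostics.
#' @export
sample_mutational_moments <- function(record, gene_class = c("a", "c"),
                                      n_samples = 1e5, mut_var = NULL) {
  gene_class <- match.arg(gene_class)
  stopifnot(n_samples >= 2)
  if (inherits(record, "population")) {
    pops <- list(record)
    mut_var <- mut_var %||% 0.5
  } else {
    stopifnot(inherits(record, "sim_record"))
    if (length(record$snapshots) < 1) stop("record has no snapshots")
    pops <- lapply(record$snapshots, `[[`, "population")
    mut_var <- mut_var %||% record$params$mut_var
  }
  nt <- pops[[1]]$n_traits; na <- pops[[1]]$n_a; nc <- nt * na
  n_samples <- as.integer(n_samples)

  snap <- sample.int(length(pops), n_samples, replace = TRUE)
  ind <- sample.int(pops[[1]]$N, n_samples, replace = TRUE)
  n_genes <- if (gene_class == "a") na else nc
  gene <- sample.int(n_genes, n_samples, replace = TRUE)
  delta <- rnorm(n_samples, 0, sqrt(mut_var))

  z <- matrix(0, nt, n_samples)
  dz <- matrix(0, nt, n_samples)
  zcache <- lapply(pops, pop_phenotypes)
  for (s in seq_along(pops)) {
    sel <- which(snap == s)
    if (!length(sel)) next
    pop <- pops[[s]]
    z[, sel] <- zcache[[s]][, ind[sel], drop = FALSE]
    if (gene_class == "a") {
      # an a_j perturbation moves every trait through column j of c
      lin <- outer(seq_len(nt), (ind[sel] - 1L) * nc + (gene[sel] - 1L) * nt,
                   `+`)
      dz[, sel] <- matrix(pop$c[lin], nt, length(sel)) *
        rep(delta[sel], each = nt)
    } else {
      # a c_ij perturbation moves only trait i, by delta * a_j
      trait <- (gene[sel] - 1L) %% nt + 1L
      gj <- (gene[sel] - 1L) %/% nt + 1L
      aval <- pop$a[cbind(gj, ind[sel])]
      dz[cbind(trait, sel)] <- delta[sel] * aval
    }
  }
  czd <- cov(t(z), t(dz))
  M <- cov(t(dz)) + czd + t(czd)
  dimnames(M) <- NULL
  structure(list(M_star = M, gene_class = gene_class,
                 n_samples = n_samples, z = z, dz = dz),
            class = "mutational_moments")
}

#' @export
print.mutational_moments <- function(x, ...) {
  cat("M* (", x$gene_class, "-class, ", format(x$n_samples, big.mark = ","),
      " samples)\n", sep = "")
  print(x$M_star, ...)
  invisible(x)
}

#' Total mutational variance--covariance matrix
#'
#' Combines the per-mutation a-class and c-class matrices, weighting each
#' by its genomic mutation rate: M_tot = n_a mu_a M*_a + (n_traits n_a)
#' mu_c M*_c. With the defaults (4 weight genes, 16 contribution genes)
#' this is the 4 mu_a / 16 mu_c weighting.
#'
#' @param Ma `mutational_moments` for class "a".
#' @param Mc `mutational_moments` for class "c".
#' @param params a `model_params` supplying the rates and gene counts.
#' @return a `vcv_matrix` labelled "mutational".
#' @export
total_mutational_matrix <- function(Ma, Mc, params) {
  stopifnot(inherits(Ma, "mutational_moments"),
            inherits(Mc, "mutational_moments"))
  if (Ma$gene_class != "a" || Mc$gene_class != "c")
    stop("Ma must be a-class and Mc must be c-class")
  if (!all(dim(Ma$M_star) == dim(Mc$M_star)))
    stop("moment matrices have mismatched dimensions")
  m <- params$n_a * params$mu_a * Ma$M_star +
    params$n_traits * params$n_a * params$mu_c * Mc$M_star
  vcv_matrix(m, "mutational")
}

#' Tidy table of mutational moments across replicates
#' @param moments named list (per replicate) of lists with elements `a`
#'   and `c` (`mutational_moments`) and optionally `total` (`vcv_matrix`).
#' @param pattern environment pattern label for the table.
#' @return data.frame with replicate, pattern, label, gene_class, trait_i,
#'   trait_j, value.
#' @export
mutational_tidy <- function(moments, pattern = NA_character_) {
  rows <- list()
  for (r in seq_along(moments)) {
    mm <- moments[[r]]
    add <- function(m, gc) {
      nt <- nrow(m)
      data.frame(replicate = r, pattern = pattern, label = "mutational",
                 gene_class = gc,
                 trait_i = rep(seq_len(nt), nt),
                 trait_j = rep(seq_len(nt), each = nt),
                 value = as.vector(unclass(m)))
    }
    rows[[length(rows) + 1L]] <- add(mm$a$M_star, "a")
    rows[[length(rows) + 1L]] <- add(mm$c$M_star, "c")
    if (!is.null(mm$total))
      rows[[length(rows) + 1L]] <- add(mm$total, "total")
  }
  do.call(rbind, rows)
}
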