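#' Population container
#'
#' A population holds N genotypes column-wise: `a` is `n_a` x N and `c` is
#' `(n_traits * n_a)` x N, each column the column-major flattening of one
#' individual's contribution matrix (row of trait i, gene j at index
#' `(j - 1) * n_traits + i`).
#'
#' @param a numeric matrix `n_a` x N of weight alleles.
#' @param cflat numeric matrix `(n_traits * n_a)` x N of contribution alleles.
#' @param n_traits number of traits.
#' @return an object of class `population`.
#' @export
population <- function(a, cflat, n_traits) {
  a <- as.matrix(a); cflat <- as.matrix(cflat)
  if (ncol(a) != ncol(cflat))
    stop("a and c describe different numbers of individuals")
  if (nrow(cflat) != n_traits * nrow(a))
    stop("c has ", nrow(cflat), " rows; expected n_traits * n_a = ",
         n_traits * nrow(a))
  structure(list(a = a, c = cflat, n_traits = as.integer(n_traits),
                 n_a = nrow(a), N = ncol(a)),
            class = "population")
}

#' A genetically uniform population
#'
#' Every individual carries the same genotype (all-zero alleles by default,
#' placing the phenotype at the origin).
#'
#' @param params a `model_params`.
#' @param g optional `genotype` to replicate; defaults to all zeros.
#' @return a `population`.
#' @export
uniform_population <- function(params, g = NULL) {
  if (is.null(g))
    g <- genotype(rep(0, params$n_a),
                  matrix(0, params$n_traits, params$n_a))
  population(matrix(g$a, params$n_a, params$N),
             matrix(as.vector(g$c), params$n_traits * params$n_a, params$N),
             params$n_traits)
}

#' Extract one individual as a genotype
#' @param pop a `population`.
#' @param k individual index.
#' @return a `genotype`.
#' @export
get_genotype <- function(pop, k) {
  genotype(pop$a[, k], matrix(pop$c[, k], pop$n_traits, pop$n_a))
}

#' Phenotypes of all individuals
#'
#' @param pop a `population`.
#' @return numeric matrix `n_traits` x N of trait values.
#' @export
pop_phenotypes <- function(pop) {
  cz <- pop$c * pop$a[rep(seq_len(pop$n_a), each = pop$n_traits), ,
                      drop = FALSE]
  z <- rowsum(cz, group = rep(seq_len(pop$n_traits), pop$n_a))
  dimnames(z) <- NULL
  z
}

#' Fitness of all individuals at an optimum
#' @param pop a `population`.
#' @param opt optimum vector of length `n_traits`.
#' @param selection_var per-trait variance of the Gaussian fitness function.
#' @return numeric vector of N fitnesses in (0, 1].
#' @export
pop_fitness <- function(pop, opt, selection_var = 1) {
  z <- pop_phenotypes(pop)
  exp(-colSums((z - opt)^2) / (2 * selection_var))
}

#' Test-fixture populations with known covariance structure
#'
#' Constructs small populations whose pleiotropy/LD structure is known by
#' construction, for validating the estimators:
#' \describe{
#'   \item{uniform}{all genotypes identical; every (co)variance is zero.}
#'   \item{no_ld}{every locus drawn independently across individuals
#'     (iid Normal), so linkage disequilibrium is zero in expectation.}
#'   \item{perfect_coupling}{two traits, two weight genes, identity
#'     contribution matrix shared by all; the two weight loci carry
#'     identical 0/1 allele sequences (half the population each), giving
#'     trait covariance 0.25 entirely from linkage disequilibrium.}
#'   \item{fixed_c}{one shared contribution matrix, weight alleles iid
#'     Normal: a purely additive map (heritability 1).}
#' }
#'
#' @param kind one of "uniform", "no_ld", "perfect_coupling", "fixed_c".
#' @param N number of individuals (even for perfect_coupling).
#' @param n_traits,n_a dimensions (forced to 2 x 2 for perfect_coupling).
#' @param cmat optional shared contribution matrix for "fixed_c".
#' @param a_sd standard deviation of iid weight alleles where drawn.
#' @return a `population` with attribute `fixture_kind`.
#' @export
make_fixture <- function(kind = c("uniform", "no_ld", "perfect_coupling",
                                  "fixed_c"),
                         N = 200, n_traits = 4, n_a = 4, cmat = NULL,
                         a_sd = 1) {
  kind <- match.arg(kind)
  nc <- n_traits * n_a
  pop <- switch(kind,
    uniform = {
      g <- genotype(rnorm(n_a), matrix(rnorm(nc), n_traits, n_a))
      population(matrix(g$a, n_a, N), matrix(as.vector(g$c), nc, N), n_traits)
    },
    no_ld = {
      population(matrix(rnorm(n_a * N, 0, a_sd), n_a, N),
                 matrix(rnorm(nc * N, 0, a_sd), nc, N), n_traits)
    },
    perfect_coupling = {
      stopifnot(N %% 2 == 0)
      half <- sample(rep(c(0, 1), N / 2)) # shuffled half-and-half
      a <- rbind(half, half)
      dimnames(a) <- NULL
      population(a, matrix(as.vector(diag(2)), 4, N), 2)
    },
    fixed_c = {
      if (is.null(cmat))
        cmat <- matrix(runif(nc, 0.5, 1.5), n_traits, n_a)
      population(matrix(rnorm(n_a * N, 0, a_sd), n_a, N),
                 matrix(as.vector(cmat), length(cmat), N), nrow(cmat))
    })
  attr(pop, "fixture_kind") <- kind
  pop
}
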