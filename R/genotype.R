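#' Model parameters
#'
#' Bundles the demographic and mutational parameters of the model. Defaults
#' follow the standard configuration: four traits, four weight genes (so 20
#' genes in total), mutation rates tuned so that an N = 1000 population
#' receives on average 5 weight-gene and 5 contribution-gene mutations per
#' generation, mutational effects drawn from Normal(0, variance 0.5), and a
#' Gaussian fitness function with per-trait variance 1.
#'
#' @param N population size (constant through time), integer >= 2.
#' @param n_traits number of quantitative traits.
#' @param n_a number of weight genes.
#' @param mu_a per-gene per-birth mutation probability for weight genes.
#' @param mu_c per-gene per-birth mutation probability for contribution genes.
#' @param mut_var variance of the Normal mutational effect distribution.
#' @param sexual logical; sexual reproduction with free recombination?
#' @param selection_var variance of the Gaussian fitness function per trait.
#' @return an object of class `model_params`.
#' @export
model_params <- function(N = 1000, n_traits = 4, n_a = 4,
                         mu_a = 1.25e-3, mu_c = 3.125e-4,
                         mut_var = 0.5, sexual = FALSE,
                         selection_var = 1) {
  stopifnot(N >= 2, n_traits >= 1, n_a >= 1,
            mu_a >= 0, mu_a <= 1, mu_c >= 0, mu_c <= 1,
            mut_var > 0, selection_var > 0)
  structure(list(N = as.integer(N), n_traits = as.integer(n_traits),
                 n_a = as.integer(n_a), mu_a = mu_a, mu_c = mu_c,
                 mut_var = mut_var, sexual = isTRUE(sexual),
                 selection_var = selection_var),
            class = "model_params")
}

#' Construct a genotype
#'
#' A genotype is a weight vector `a` (length `n_a`) plus a contribution
#' matrix `c` (`n_traits` x `n_a`); entry `c[i, j]` is the effect of weight
#' gene j on trait i. All alleles are unbounded reals.
#'
#' @param a numeric vector of weight-gene alleles.
#' @param cmat numeric contribution matrix, `n_traits` rows x `length(a)` columns.
#' @return an object of class `genotype`.
#' @export
genotype <- function(a, cmat) {
  a <- as.numeric(a)
  cmat <- as.matrix(cmat)
  if (ncol(cmat) != length(a))
    stop("contribution matrix has ", ncol(cmat), " columns but a has ",
         length(a), " entries")
  if (!all(is.finite(a)) || !all(is.finite(cmat)))
    stop("genotype contains non-finite alleles")
  structure(list(a = a, c = cmat), class = "genotype")
}

#' Genotype to phenotype map
#'
#' The phenotype is the linear read-out of the weight genes through the
#' contribution matrix: z_i = sum_j c_ij a_j.
#'
#' @param g a `genotype`.
#' @return numeric vector of trait values, length `n_traits`.
#' @export
compute_phenotype <- function(g) {
  stopifnot(inherits(g, "genotype"))
  as.vector(g$c %*% g$a)
}

#' Gaussian fitness
#'
#' Fitness is multiplicative across traits with a Gaussian profile per trait:
#' w(z) = exp(-sum_i (z_i - opt_i)^2 / (2 * selection_var)). There is no
#' correlational selection within a generation; log-fitness is additively
#' separable over per-trait deviations.
#'
#' @param z phenotype vector.
#' @param opt optimum vector, same length as `z`.
#' @param selection_var per-trait variance of the fitness function.
#' @return fitness in (0, 1].
#' @export
fitness <- function(z, opt, selection_var = 1) {
  if (length(z) != length(opt))
    stop("phenotype has length ", length(z), " but optimum has length ",
         length(opt))
  exp(-sum((z - opt)^2) / (2 * selection_var))
}

#' Mutate a genotype
#'
#' Each weight gene mutates independently with probability `mu_a`, each
#' contribution gene with probability `mu_c`; a mutated allele is the
#' parental value plus a Normal(0, `mut_var`) draw. The input genotype is
#' untouched; a new genotype is returned. Randomness comes from R's global
#' RNG stream.
#'
#' @param g a `genotype`.
#' @param params a `model_params` (only `mu_a`, `mu_c`, `mut_var` are used).
#' @return the mutated `genotype`.
#' @export
mutate_genotype <- function(g, params) {
  stopifnot(inherits(g, "genotype"))
  sd <- sqrt(params$mut_var)
  hit_a <- runif(length(g$a)) < params$mu_a
  if (any(hit_a)) g$a[hit_a] <- g$a[hit_a] + rnorm(sum(hit_a), 0, sd)
  hit_c <- runif(length(g$c)) < params$mu_c
  if (any(hit_c)) g$c[hit_c] <- g$c[hit_c] + rnorm(sum(hit_c), 0, sd)
  g
}

#' Free recombination of two genotypes
#'
#' Every heritable element (each weight allele and each contribution allele
#' independently) comes from either parent with probability 1/2.
#'
#' @param p1,p2 parental `genotype`s with identical dimensions.
#' @return the offspring `genotype`.
#' @export
recombine <- function(p1, p2) {
  stopifnot(inherits(p1, "genotype"), inherits(p2, "genotype"))
  if (length(p1$a) != length(p2$a) || !all(dim(p1$c) == dim(p2$c)))
    stop("parents have mismatched genome dimensions")
  from2a <- runif(length(p1$a)) < 0.5
  p1$a[from2a] <- p2$a[from2a]
  from2c <- runif(length(p1$c)) < 0.5
  p1$c[from2c] <- p2$c[from2c]
  p1
}
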