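#' @include accessors.R
NULL

#' Simulate a dominant-marker dataset with known truth
#'
#' Generative mirror of the hierarchical model used for Bayesian inference on
#' dominant data. For each locus \eqn{l} with ancestral dominant-allele
#' frequency \eqn{\pi_l}, every population \eqn{k} draws its own frequency
#' \deqn{p_{kl} \sim Beta(\pi_l (1-\theta)/\theta, (1-\pi_l)(1-\theta)/\theta)}
#' (so that across populations \eqn{E[p_{kl}] = \pi_l} and
#' \eqn{Var[p_{kl}] = \theta \pi_l (1-\pi_l)}); with \eqn{\theta = 0} the
#' frequencies equal \eqn{\pi_l} exactly. Each individual then shows no band
#' (null homozygote) with probability \eqn{q^2 + f q (1-q)} where
#' \eqn{q = 1 - p}, the inbreeding-adjusted Hardy-Weinberg null-homozygote
#' frequency.
#'
#' @param n_pops number of populations.
#' @param n_per_pop integer vector of per-population sample sizes (recycled
#'   to \code{n_pops}).
#' @param n_loci number of loci.
#' @param pi ancestral dominant-allele frequencies: either a numeric vector
#'   of length \code{n_loci} (values in (0,1)) or a two-element range from
#'   which frequencies are drawn uniformly (default \code{c(0.05, 0.95)},
#'   which keeps loci away from monomorphism).
#' @param theta differentiation used to disperse population frequencies,
#'   in [0, 1).
#' @param f within-population inbreeding coefficient, in [0, 1].
#' @param seed integer seed; the run is fully reproducible given it.
#' @param pop_names optional population labels.
#' @param primer_sizes optional integer vector of loci-per-primer counts
#'   (must sum to \code{n_loci}); attaches a primer panel.
#' @return list with elements \code{matrix} (a \linkS4class{BandMatrix}) and
#'   \code{truth} (a \linkS4class{SimulationTruth}).
#' @examples
#' sim <- simulateDominant(4, 10, 50, theta = 0.1, f = 0, seed = 1)
#' sim$matrix
#' @export
simulateDominant <- function(n_pops, n_per_pop, n_loci,
                             pi = c(0.05, 0.95), theta = 0.19, f = 0.14,
                             seed, pop_names = NULL, primer_sizes = NULL) {
  stopifnot(n_pops >= 1, n_loci >= 1, all(n_per_pop >= 1))
  if (theta < 0 || theta >= 1)
    stop("theta must be in [0, 1); theta = 1 gives a degenerate Beta")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(n_pops))

  piL <- if (length(pi) == n_loci) pi
         else if (length(pi) == 2L) runif(n_loci, pi[1L], pi[2L])
         else if (length(pi) == 1L) rep(pi, n_loci)
         else stop("'pi' must be a range, a scalar or one value per locus")
  if (any(piL <= 0 | piL >= 1))
    stop("ancestral frequencies must lie strictly inside (0, 1)")

  if (theta == 0) {
    popFreq <- matrix(rep(piL, each = n_pops), n_pops, n_loci)
  } else {
    conc <- (1 - theta) / theta
    popFreq <- matrix(rbeta(n_pops * n_loci,
                            shape1 = rep(piL * conc, each = n_pops),
                            shape2 = rep((1 - piL) * conc, each = n_pops)),
                      n_pops, n_loci)
  }
  dimnames(popFreq) <- list(pop_names, paste0("L", seq_len(n_loci)))

  q <- 1 - popFreq
  pAbsent <- q^2 + f * q * (1 - q)       # null-homozygote probability
  calls <- matrix(0L, sum(n_per_pop), n_loci)
  popLab <- rep(pop_names, times = n_per_pop)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    nk <- n_per_pop[k]
    absent <- matrix(rbinom(nk * n_loci, 1L, rep(pAbsent[k, ], each = nk)),
                     nk, n_loci)
    calls[row0 + seq_len(nk), ] <- 1L - absent
    row0 <- row0 + nk
  }
  rownames(calls) <- paste0(popLab, "_", unlist(lapply(n_per_pop, seq_len)))
  colnames(calls) <- colnames(popFreq)

  primer <- NULL
  if (!is.null(primer_sizes)) {
    stopifnot(sum(primer_sizes) == n_loci)
    primer <- rep(paste0("primer", seq_along(primer_sizes)),
                  times = primer_sizes)
  }
  truth <- new("SimulationTruth", pi = piL, theta = theta, f = f,
               popFreq = popFreq, seed = as.integer(seed))
  list(matrix = BandMatrix(calls, population = popLab, primer = primer),
       truth = truth)
}

#' Simulate a dataset shaped like the reference ISSR study
#'
#' Eight populations named as in the reference study with sample sizes
#' (YMF 20, FHB 23, SDG 20, SEG 23, XV 23, TF 21, WZT 19, SP 23; 172
#' individuals in total) scored at 180 loci grouped into the ten observed
#' primer band counts (19, 22, 18, 18, 16, 17, 20, 10, 19, 21). The
#' generator's differentiation and inbreeding defaults, theta = 0.19 and
#' f = 0.14, are the study's own estimates, so parameter-recovery checks run
#' under realistic conditions.
#'
#' @param seed integer seed.
#' @param theta,f overrides for the study-level defaults.
#' @return as \code{\link{simulateDominant}}.
#' @export
studyLikeDataset <- function(seed, theta = 0.19, f = 0.14) {
  sizes <- c(YMF = 20L, FHB = 23L, SDG = 20L, SEG = 23L, XV = 23L,
             TF = 21L, WZT = 19L, SP = 23L)
  bands <- c(19L, 22L, 18L, 18L, 16L, 17L, 20L, 10L, 19L, 21L)
  simulateDominant(n_pops = 8L, n_per_pop = unname(sizes), n_loci = 180L,
                   theta = theta, f = f, seed = seed,
                   pop_names = names(sizes), primer_sizes = bands)
}
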