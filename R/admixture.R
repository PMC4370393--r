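#' @include hickory.R
NULL

#' Admixture-model clustering of haploid-coded bands
#'
#' Gibbs sampler for the admixture model on dominant data coded as one
#' haploid biallelic locus per band. Cluster band frequencies carry
#' independent Beta(1,1) priors, each individual's ancestry vector
#' \eqn{Q_i} a symmetric Dirichlet(1) prior, and a latent cluster of origin
#' is sampled for every individual-locus call. The log probability of the
#' data for the run is estimated from the chain of log-likelihoods
#' \eqn{\ln L_t} (with the latent origins integrated out) as
#' \eqn{\widehat{\ln P} = \bar{\ln L} - \mathrm{var}(\ln L)/2}, the standard
#' harmonic-style estimate used for choosing K.
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param K number of clusters (1 <= K <= number of individuals).
#' @param burn_in,reps burn-in and post-burn-in sweep counts; the defaults
#'   (10000 / 100000) suit final analyses, tests use much shorter chains.
#' @param seed integer seed (required).
#' @param n_replicates number of independent runs (seeds derived from
#'   \code{seed}); each yields one \linkS4class{AdmixtureResult}.
#' @return a single \linkS4class{AdmixtureResult}, or a list of them when
#'   \code{n_replicates > 1}.
#' @export
setMethod("fitAdmixture", "BandMatrix",
  function(x, K, burn_in = 10000L, reps = 100000L, seed,
           n_replicates = 1L) {
    if (missing(seed)) stop("a seed is required")
    if (K < 1L) stop("K must be at least 1")
    if (K > nIndividuals(x)) stop("K exceeds the number of individuals")
    if (n_replicates > 1L) {
      out <- lapply(seq_len(n_replicates), function(r)
        fitAdmixture(x, K = K, burn_in = burn_in, reps = reps,
                     seed = as.integer(seed) + 7919L * (r - 1L)))
      return(out)
    }
    set.seed(as.integer(seed))
    m <- bandCalls(x)                    # individuals x loci
    N <- nrow(m); L <- ncol(m)
    obs <- !is.na(m)
    x1 <- m == 1L & obs

    if (K == 1L) {
      ## degenerate case: everything from the single cluster
      pHat <- matrix(clampP((colSums(x1) + 1) / (colSums(obs) + 2)),
                     N, L, byrow = TRUE)
      lnLik <- sum(log(ifelse(x1, pHat, 1 - pHat))[obs])
      return(new("AdmixtureResult", K = 1L,
                 Q = matrix(1, N, 1, dimnames = list(rownames(m), "c1")),
                 lnP = lnLik,
                 settings = list(burn_in = burn_in, reps = reps,
                                 seed = as.integer(seed))))
    }

    ## state
    p <- matrix(runif(K * L, 0.2, 0.8), K, L)     # cluster band frequencies
    Q <- matrix(1 / K, N, K)
    qSum <- matrix(0, N, K)
    lnL <- numeric(reps)
    nIter <- burn_in + reps
    for (it in seq_len(nIter)) {
      ## latent origins z | Q, p  (sampled jointly over i, l)
      ## P(z=c | x) propto Q_ic * p_cl^x (1-p_cl)^(1-x)
      logp <- log(clampP(p)); log1mp <- log1p(-clampP(p))
      wm <- matrix(0, N * L, K)
      for (c in seq_len(K))
        wm[, c] <- log(Q[, c]) +                       # recycles over loci
          as.vector(x1 * rep(logp[c, ], each = N) +
                    (!x1) * rep(log1mp[c, ], each = N))
      ## Gumbel-max trick for categorical sampling
      wm <- wm - log(-log(runif(N * L * K)))
      z <- max.col(wm, ties.method = "first")
      dim(z) <- c(N, L)
      z[!obs] <- NA_integer_
      ## p | z, x  : Beta(1 + n1, 1 + n0) per cluster-locus
      for (c in seq_len(K)) {
        inC <- z == c & obs
        a <- colSums(x1 & inC) + 1
        b <- colSums(inC & !x1) + 1
        p[c, ] <- rbeta(L, a, b)
      }
      ## Q | z : Dirichlet(1 + counts)
      cnt <- matrix(0, N, K)
      for (c in seq_len(K)) cnt[, c] <- rowSums(z == c, na.rm = TRUE)
      gmat <- matrix(rgamma(N * K, shape = cnt + 1, rate = 1), N, K)
      Q <- gmat / rowSums(gmat)
      if (it > burn_in) {
        qSum <- qSum + Q
        ## mixture log-likelihood with z integrated out
        lik <- matrix(0, N, L)
        for (c in seq_len(K)) {
          pc <- matrix(clampP(p[c, ]), N, L, byrow = TRUE)
          lik <- lik + Q[, c] * ifelse(x1, pc, 1 - pc)
        }
        lnL[it - burn_in] <- sum(log(lik[obs]))
      }
    }
    Qhat <- qSum / reps
    Qhat <- Qhat / rowSums(Qhat)
    dimnames(Qhat) <- list(rownames(m), paste0("c", seq_len(K)))
    new("AdmixtureResult", K = as.integer(K), Q = Qhat,
        lnP = mean(lnL) - var(lnL) / 2,
        settings = list(burn_in = burn_in, reps = reps,
                        seed = as.integer(seed)))
  })

#' Ancestry matrix of an admixture fit
#'
#' @param x an \linkS4class{AdmixtureResult}.
#' @return the posterior-mean Q matrix (rows sum to 1).
#' @export
ancestryQ <- function(x) x@Q

#' @rdname ancestryQ
#' @export
lnProbData <- function(x) x@lnP

#' Evanno delta-K from replicate log-probabilities
#'
#' \eqn{\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / sd(L(K))},
#' the absolute second difference of the mean log probability scaled by the
#' between-replicate standard deviation; undefined at the smallest and
#' largest K, which are omitted rather than extrapolated. The optimal K is
#' the interior K maximising delta-K.
#'
#' @param table data.frame with columns \code{K} and \code{lnP}, one row
#'   per replicate run (>= 2 replicates per K, >= 3 consecutive K values).
#' @return an \linkS4class{EvannoTable}.
#' @export
evannoDeltaK <- function(table) {
  stopifnot(all(c("K", "lnP") %in% names(table)))
  ks <- sort(unique(table$K))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1L)) stop("K values must be consecutive")
  mn <- tapply(table$lnP, table$K, mean)[as.character(ks)]
  sdv <- tapply(table$lnP, table$K, sd)[as.character(ks)]
  nr <- tapply(table$lnP, table$K, length)[as.character(ks)]
  if (any(nr < 2L)) stop("need >= 2 replicates at every K")
  inner <- seq(2L, length(ks) - 1L)
  if (any(sdv[inner] == 0))
    stop("zero replicate sd at K = ",
         paste(ks[inner][sdv[inner] == 0], collapse = ", "))
  dk <- rep(NA_real_, length(ks))
  dk[inner] <- abs(mn[inner + 1L] - 2 * mn[inner] + mn[inner - 1L]) /
    sdv[inner]
  tab <- data.frame(K = ks, n_reps = as.integer(nr), mean_lnP = as.numeric(mn),
                    sd_lnP = as.numeric(sdv), deltaK = dk)
  best <- ks[inner][which.max(dk[inner])]
  new("EvannoTable", table = tab, optimalK = as.integer(best))
}

#' Assign individuals to clusters from ancestry fractions
#'
#' An individual is confidently assigned to the cluster whose ancestry
#' fraction reaches \code{threshold} (inclusive); otherwise it is labelled
#' \code{"admixed"}.
#'
#' @param q ancestry matrix (rows sum to 1) or an
#'   \linkS4class{AdmixtureResult}.
#' @param threshold assignment threshold (default 0.8).
#' @return list: \code{assignment} (character vector, cluster column name or
#'   "admixed"), \code{summary} (percent of individuals per cluster and
#'   percent admixed).
#' @export
assignIndividuals <- function(q, threshold = 0.8) {
  if (is(q, "AdmixtureResult")) q <- q@Q
  if (any(abs(rowSums(q) - 1) > 1e-9))
    stop("ancestry rows must sum to 1")
  if (is.null(colnames(q))) colnames(q) <- paste0("c", seq_len(ncol(q)))
  top <- max.col(q, ties.method = "first")
  hit <- q[cbind(seq_len(nrow(q)), top)] >= threshold
  assignment <- ifelse(hit, colnames(q)[top], "admixed")
  names(assignment) <- rownames(q)
  lev <- c(colnames(q), "admixed")
  pct <- 100 * table(factor(assignment, levels = lev)) / nrow(q)
  list(assignment = assignment, summary = as.numeric(pct) |>
         setNames(lev))
}
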