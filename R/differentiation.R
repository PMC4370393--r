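#' @include diversity.R
NULL

#' Nei's Gst from dominant-marker allele frequencies
#'
#' Per locus, total gene diversity \eqn{H_t = 2\bar p \bar q} on the
#' unweighted mean allele frequencies across populations and mean
#' within-population diversity \eqn{H_s = \overline{2 p_k q_k}}; the
#' genome-wide value is the ratio of sums
#' \eqn{G_{st} = \sum_l (H_t - H_s) / \sum_l H_t} (0 when every locus has
#' \eqn{H_t = 0}).
#'
#' @param x a \linkS4class{BandMatrix} with >= 2 populations.
#' @return Gst in [0, 1].
#' @export
setMethod("gstDominant", "BandMatrix", function(x) {
  pb <- popBandFreq(x)
  if (length(pb$pops) < 2L) stop("at least 2 populations are required")
  q <- nullAlleleFreq(pb$freq)           # pops x loci
  p <- 1 - q
  pbar <- colMeans(p)
  Ht <- 2 * pbar * (1 - pbar)
  Hs <- colMeans(2 * p * q)
  if (sum(Ht) == 0) return(0)
  sum(Ht - Hs) / sum(Ht)
})

# Squared-Euclidean (band mismatch) distances between individuals; missing
# calls are ignored pairwise.
bandMismatch <- function(x) {
  m <- bandCalls(x)
  if (anyNA(m)) {
    d2 <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d2[i, j] <- d2[j, i] <- sum((m[i, ok] - m[j, ok])^2)
    }
    d2
  } else {
    as.matrix(stats::dist(m, method = "euclidean"))^2
  }
}

# AMOVA decomposition from a matrix of squared distances and group labels.
amovaComponents <- function(d2, groups) {
  g <- factor(groups)
  N <- length(g)
  G <- nlevels(g)
  ssdTotal <- sum(d2) / (2 * N)
  ssdWithin <- 0
  for (lev in levels(g)) {
    i <- which(g == lev)
    ssdWithin <- ssdWithin + sum(d2[i, i]) / (2 * length(i))
  }
  ssdAmong <- ssdTotal - ssdWithin
  dfAmong <- G - 1L
  dfWithin <- N - G
  ng <- tabulate(g)
  n0 <- (N - sum(ng^2) / N) / dfAmong
  sigmaW <- ssdWithin / dfWithin
  sigmaA <- (ssdAmong / dfAmong - sigmaW) / n0
  tot <- sigmaA + sigmaW
  list(ssd = c(among = ssdAmong, within = ssdWithin, total = ssdTotal),
       df = c(among = dfAmong, within = dfWithin),
       sigma2 = c(among = sigmaA, within = sigmaW),
       phiST = if (tot == 0) NA_real_ else sigmaA / tot)
}

#' Analysis of molecular variance for dominant markers
#'
#' One-level AMOVA in the Excoffier framework: the inter-individual distance
#' is the squared Euclidean distance between band vectors (the count of
#' differing non-missing calls); sums of squared deviations are partitioned
#' within/among populations and variance components extracted from the
#' expected mean squares with the usual unequal-sample-size coefficient
#' \eqn{n_0}. Significance of \eqn{\Phi_{st}} comes from permuting
#' individuals across populations, with the observed statistic included in
#' both numerator and denominator of the p-value.
#'
#' @param x a \linkS4class{BandMatrix} (>= 2 populations, >= 2 individuals
#'   each).
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed integer seed for the permutations (required when
#'   \code{n_perm > 0}).
#' @return an \linkS4class{AmovaResult}.
#' @export
setMethod("amova", "BandMatrix", function(x, n_perm = 1000L, seed = NULL) {
  pop <- populations(x)
  sizes <- table(pop)
  if (length(sizes) < 2L) stop("at least 2 populations are required")
  if (any(sizes < 2L)) stop("every population needs >= 2 individuals")
  d2 <- bandMismatch(x)
  obs <- amovaComponents(d2, pop)
  if (is.na(obs$phiST))
    warning("total SSD is zero; Phi-ST undefined")
  p <- NA_real_
  if (n_perm > 0L && !is.na(obs$phiST)) {
    if (is.null(seed)) stop("a seed is required for the permutation test")
    set.seed(as.integer(seed))
    hits <- 1L   # observed included
    for (b in seq_len(n_perm)) {
      phi <- amovaComponents(d2, sample(pop))$phiST
      if (!is.na(phi) && phi >= obs$phiST) hits <- hits + 1L
    }
    p <- hits / (n_perm + 1L)
  }
  tot <- sum(obs$sigma2)
  new("AmovaResult", ssd = obs$ssd, df = obs$df, sigma2 = obs$sigma2,
      percent = 100 * obs$sigma2 / tot, phiST = obs$phiST, pValue = p,
      nPerm = as.integer(n_perm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
})

#' Accessors for AmovaResult
#'
#' @param x an \linkS4class{AmovaResult}.
#' @return \code{phiST}: the Phi-statistic; \code{amovaTable}: the classic
#'   df/SSD/variance-component/percent table as a data.frame.
#' @export
phiST <- function(x) x@phiST

#' @rdname phiST
#' @export
amovaTable <- function(x)
  data.frame(source = c("among", "within"), df = unname(x@df),
             SSD = unname(x@ssd[c("among", "within")]),
             sigma2 = unname(x@sigma2), percent = unname(x@percent),
             stringsAsFactors = FALSE)

#' @rdname phiST
#' @export
amovaPValue <- function(x) x@pValue

#' Pairwise Fst between populations
#'
#' Entry (i, j) is the two-population \eqn{\Phi_{st}} from \code{\link{amova}}
#' restricted to populations i and j — the pairwise-Fst convention of
#' distance-based AMOVA software.
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param n_perm permutations per pair for p-values (0 = none).
#' @param seed integer seed.
#' @return list: \code{fst}, a \linkS4class{LabeledDistance} (units "fst"),
#'   and \code{p}, a matrix of permutation p-values (NA without
#'   permutations).
#' @export
setMethod("pairwiseFst", "BandMatrix",
  function(x, n_perm = 0L, seed = NULL) {
    pops <- populationNames(x)
    if (length(pops) < 2L) stop("at least 2 populations are required")
    k <- length(pops)
    fst <- matrix(0, k, k, dimnames = list(pops, pops))
    pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      sub <- subsetPopulations(x, pops[c(i, j)])
      res <- amova(sub, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL
                          else as.integer(seed) + 1000L * i + j)
      fst[i, j] <- fst[j, i] <- res@phiST
      pv[i, j] <- pv[j, i] <- res@pValue
    }
    list(fst = LabeledDistance(fst, units = "fst"), p = pv)
  })

#' Indirect gene-flow estimate from Fst
#'
#' Wright's island-model relation \eqn{N_m = (1 - F_{st}) / (4 F_{st})},
#' the effective number of migrants per generation implied by a given level
#' of differentiation. Strictly decreasing in Fst.
#'
#' @param fst differentiation in (0, 1).
#' @return Nm (vectorised).
#' @examples
#' geneFlow(0.2)  # 1 migrant per generation
#' @export
geneFlow <- function(fst) {
  if (any(fst <= 0 | fst >= 1))
    stop("Fst must lie strictly inside (0, 1)")
  (1 - fst) / (4 * fst)
}

#' Pairwise linkage-disequilibrium screen
#'
#' Two-sided Fisher's exact test of association on the 2x2 table of joint
#' band presence/absence for every pair of polymorphic loci, pooled over
#' populations. The percent significant is reported rounded to one decimal.
#' By default pairs are unordered (\eqn{\binom{L}{2}}); the \code{"ordered"}
#' convention counts every ordered pair (\eqn{L^2}, each association twice
#' plus the L self-pairs, which are not tested), reproducing the denominator
#' convention of some published reports.
#'
#' @param x a \linkS4class{BandMatrix} with >= 2 polymorphic loci.
#' @param alpha significance level (default 0.05).
#' @param pair_convention \code{"unordered"} (default) or \code{"ordered"}.
#' @return list: n_pairs_tested, n_significant, percent, n_monomorphic
#'   (loci excluded), alpha.
#' @export
setMethod("ldScreen", "BandMatrix",
  function(x, alpha = 0.05, pair_convention = c("unordered", "ordered")) {
    pair_convention <- match.arg(pair_convention)
    m <- bandCalls(x)
    fb <- bandFrequency(x)
    poly <- fb > 0 & fb < 1
    nMono <- sum(!poly)
    m <- m[, poly, drop = FALSE]
    L <- ncol(m)
    if (L < 2L) stop("at least 2 polymorphic loci are required")
    sig <- 0L
    for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      tab <- table(factor(m[ok, i], levels = 0:1),
                   factor(m[ok, j], levels = 0:1))
      if (fisher.test(tab)$p.value <= alpha) sig <- sig + 1L
    }
    if (pair_convention == "unordered") {
      nPairs <- L * (L - 1L) / 2L
      nSig <- sig
    } else {
      nPairs <- L * L
      nSig <- 2L * sig
    }
    list(n_pairs_tested = nPairs, n_significant = nSig,
         percent = ldPercent(nSig, nPairs), n_monomorphic = nMono,
         alpha = alpha)
  })

#' Linkage-disequilibrium percentage, report-style
#'
#' @param n_significant,n_tested counts.
#' @return percentage rounded to one decimal (745/32400 -> 2.3).
#' @export
ldPercent <- function(n_significant, n_tested)
  round(100 * n_significant / n_tested, 1L)
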