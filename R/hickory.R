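#' @include distance.R
NULL

# reflect proposals into (lo, hi); preserves proposal symmetry
reflect <- function(x, lo = 1e-9, hi = 1 - 1e-9) {
  span <- 2 * (hi - lo)
  y <- (x - lo) %% span
  lo + ifelse(y > hi - lo, span - y, y)
}

clampP <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# elementwise log-likelihood of absent/present counts given null-allele
# frequency q and inbreeding f (dominant phenotype model)
phenoLL <- function(q, f, n0, n1) {
  p0 <- clampP(q^2 + f * q * (1 - q))
  n0 * log(p0) + n1 * log1p(-p0)
}

betaShapes <- function(pi, theta) {
  conc <- (1 - theta) / theta
  list(a = (1 - pi) * conc, b = pi * conc)   # prior on q: mean 1 - pi
}

#' Bayesian hierarchical model for dominant-marker differentiation
#'
#' Fits the hierarchical beta model for dominant data by
#' Metropolis-within-Gibbs. Per locus l an ancestral dominant-allele
#' frequency \eqn{\pi_l \sim U(0,1)}; per population k a null-allele
#' frequency \eqn{q_{kl} \sim Beta} with mean \eqn{1-\pi_l} and dispersion
#' \eqn{\theta_B} (shapes scaled by \eqn{(1-\theta_B)/\theta_B}); the
#' phenotype likelihood is binomial with band-absence probability
#' \eqn{q^2 + f q(1-q)} and \eqn{f \sim U(0,1)}. Model variants:
#' \describe{
#'   \item{full}{\eqn{\theta_B} and f both estimated from the data.}
#'   \item{f0}{f fixed at 0.}
#'   \item{theta0}{\eqn{\theta_B} fixed at 0, i.e. all populations share
#'     the frequency \eqn{1-\pi_l}; \eqn{\theta_I} is then identically 0.}
#'   \item{ffree}{f drawn fresh from its prior every iteration, ignoring
#'     the data — a device for diagnosing how much the data inform f.}
#' }
#' Each retained iteration records \eqn{\theta_I}, the variance-based Fst
#' analog computed from the sampled frequencies as
#' \eqn{\sum_l var_k(p_{kl}) / \sum_l \bar p_l (1 - \bar p_l)}, and the
#' per-population panmictic heterozygosity \eqn{h_s(k) = mean_l\, 2 p q}.
#' DIC uses the Spiegelhalter decomposition (mean deviance plus effective
#' parameters). Proposal widths adapt during burn-in only and are frozen
#' afterwards, so the retained chain is valid MCMC.
#'
#' @param x a \linkS4class{BandMatrix} with >= 2 populations.
#' @param variant "full", "f0", "theta0" or "ffree".
#' @param burn_in,samples,thin MCMC settings; the defaults (50000 / 250000 /
#'   50) suit final analyses, tests use much shorter chains.
#' @param seed integer seed (required).
#' @return a \linkS4class{HickoryFit}.
#' @export
setMethod("fitHickory", "BandMatrix",
  function(x, variant = c("full", "f0", "theta0", "ffree"),
           burn_in = 50000L, samples = 250000L, thin = 50L, seed) {
    variant <- match.arg(variant)
    if (missing(seed)) stop("a seed is required")
    set.seed(as.integer(seed))
    pb <- popBandFreq(x)
    K <- length(pb$pops); L <- length(pb$loci)
    if (K < 2L) stop("at least 2 populations are required")
    n <- pb$n
    n1 <- pb$freq * n          # band-present counts (pops x loci)
    n0 <- n - n1

    hasTheta <- variant != "theta0"
    fMode <- switch(variant, full = "sample", f0 = "fixed0",
                    theta0 = "sample", ffree = "prior")

    # initial state from moment estimates
    q <- matrix(pmin(pmax(sqrt((n0 + 0.5) / (n + 1)), 0.02), 0.98), K, L)
    pi <- pmin(pmax(1 - colMeans(q), 0.02), 0.98)
    theta <- 0.1
    f <- if (fMode == "fixed0") 0 else 0.1
    if (!hasTheta) q <- matrix(rep(1 - pi, each = K), K, L)

    sdQ <- 0.1; sdPi <- 0.05; sdTh <- 0.05; sdF <- 0.05
    accQ <- accPi <- accTh <- accF <- 0; cntQ <- cntPi <- cntTh <- cntF <- 0

    nIter <- burn_in + samples
    nKeep <- floor(samples / thin)
    thetaI <- thetaB <- fChain <- dev <- numeric(nKeep)
    hsKeep <- matrix(0, nKeep, K)
    kept <- 0L
    qSum <- matrix(0, K, L); fSum <- 0; piSum <- numeric(L)

    llMat <- phenoLL(q, f, n0, n1)

    for (it in seq_len(nIter)) {
      ## q update (hierarchical variants only)
      if (hasTheta) {
        sh <- betaShapes(pi, theta)
        qP <- reflect(q + matrix(rnorm(K * L, 0, sdQ), K, L))
        llP <- phenoLL(qP, f, n0, n1)
        dpr <- (rep(sh$a, each = K) - 1) * (log(qP) - log(q)) +
               (rep(sh$b, each = K) - 1) * (log1p(-qP) - log1p(-q))
        acc <- log(matrix(runif(K * L), K, L)) < (llP - llMat + dpr)
        q[acc] <- qP[acc]; llMat[acc] <- llP[acc]
        accQ <- accQ + mean(acc); cntQ <- cntQ + 1
        ## pi update: prior of q given (pi, theta), uniform prior on pi
        piP <- reflect(pi + rnorm(L, 0, sdPi))
        shP <- betaShapes(piP, theta)
        lq <- colSums(log(q)); l1q <- colSums(log1p(-q))
        logBeta <- function(a, b) lgamma(a) + lgamma(b) - lgamma(a + b)
        tgt <- function(s) (s$a - 1) * lq + (s$b - 1) * l1q -
                            K * logBeta(s$a, s$b)
        accP <- log(runif(L)) < (tgt(shP) - tgt(sh))
        pi[accP] <- piP[accP]
        accPi <- accPi + mean(accP); cntPi <- cntPi + 1
        ## theta update
        sh <- betaShapes(pi, theta)
        thP <- reflect(theta + rnorm(1, 0, sdTh), 1e-4, 1 - 1e-4)
        shT <- betaShapes(pi, thP)
        num <- sum((rep(shT$a, each = K) - 1) * log(q) +
                   (rep(shT$b, each = K) - 1) * log1p(-q)) -
               K * sum(logBeta(shT$a, shT$b))
        den <- sum((rep(sh$a, each = K) - 1) * log(q) +
                   (rep(sh$b, each = K) - 1) * log1p(-q)) -
               K * sum(logBeta(sh$a, sh$b))
        if (log(runif(1)) < num - den) { theta <- thP; accTh <- accTh + 1 }
        cntTh <- cntTh + 1
      } else {
        ## theta0: shared frequencies; random-walk on pi against likelihood
        piP <- reflect(pi + rnorm(L, 0, sdPi))
        qRowP <- 1 - piP
        llNew <- phenoLL(matrix(rep(qRowP, each = K), K, L), f, n0, n1)
        dAcc <- colSums(llNew) - colSums(llMat)
        accP <- log(runif(L)) < dAcc
        pi[accP] <- piP[accP]
        q <- matrix(rep(1 - pi, each = K), K, L)
        llMat <- phenoLL(q, f, n0, n1)
        accPi <- accPi + mean(accP); cntPi <- cntPi + 1
      }
      ## f update
      if (fMode == "sample") {
        fP <- reflect(f + rnorm(1, 0, sdF))
        llP <- phenoLL(q, fP, n0, n1)
        if (log(runif(1)) < sum(llP) - sum(llMat)) {
          f <- fP; llMat <- llP; accF <- accF + 1
        }
        cntF <- cntF + 1
      } else if (fMode == "prior") {
        f <- runif(1)
        llMat <- phenoLL(q, f, n0, n1)
      }
      ## adapt proposals during burn-in only
      if (it <= burn_in && it %% 100L == 0L) {
        tune <- function(sd, acc, cnt, target = 0.35)
          max(1e-3, min(1, sd * exp(0.5 * (acc / max(cnt, 1) - target))))
        sdQ <- tune(sdQ, accQ, cntQ); sdPi <- tune(sdPi, accPi, cntPi)
        sdTh <- tune(sdTh, accTh, cntTh); sdF <- tune(sdF, accF, cntF)
        accQ <- accPi <- accTh <- accF <- 0
        cntQ <- cntPi <- cntTh <- cntF <- 0
      }
      ## record
      if (it > burn_in && (it - burn_in) %% thin == 0L && kept < nKeep) {
        kept <- kept + 1L
        p <- 1 - q
        pbar <- colMeans(p)
        den <- sum(pbar * (1 - pbar))
        thetaI[kept] <- if (!hasTheta || den == 0) 0
                        else sum(apply(p, 2L, var)) / den
        thetaB[kept] <- if (hasTheta) theta else 0
        fChain[kept] <- f
        hsKeep[kept, ] <- rowMeans(2 * p * q)
        dev[kept] <- -2 * sum(llMat)
        qSum <- qSum + q; fSum <- fSum + f; piSum <- piSum + pi
      }
    }

    ## DIC at posterior means
    qHat <- qSum / kept
    fHat <- if (fMode == "fixed0") 0 else fSum / kept
    if (!hasTheta) qHat <- matrix(rep(1 - piSum / kept, each = K), K, L)
    dHat <- -2 * sum(phenoLL(qHat, fHat, n0, n1))
    dBar <- mean(dev)
    pD <- dBar - dHat
    dic <- dBar + pD

    summ <- function(v) c(mean = mean(v), sd = sd(v),
                          q2.5 = unname(quantile(v, 0.025)),
                          q97.5 = unname(quantile(v, 0.975)))
    sm <- rbind(thetaI = summ(thetaI), thetaB = summ(thetaB), f = summ(fChain))
    summary <- data.frame(parameter = rownames(sm), sm, row.names = NULL)
    hsTab <- do.call(rbind, lapply(seq_len(K), function(k) {
      s <- summ(hsKeep[, k])
      data.frame(population = pb$pops[k], t(s))
    }))
    new("HickoryFit", variant = variant, summary = summary, hs = hsTab,
        dic = dic, deviance = c(Dbar = dBar, Dhat = dHat, pD = pD),
        chains = list(thetaI = thetaI, thetaB = thetaB, f = fChain),
        settings = list(burn_in = burn_in, samples = samples, thin = thin,
                        seed = as.integer(seed),
                        fingerprint = c(K = K, L = L,
                                        n = sum(n), bands = sum(n1))))
  })

#' Posterior summary of a HickoryFit parameter
#'
#' @param fit a \linkS4class{HickoryFit}.
#' @param parameter "thetaI", "thetaB" or "f".
#' @return named numeric: mean, sd, q2.5, q97.5.
#' @export
posteriorSummary <- function(fit, parameter = "thetaI") {
  row <- fit@summary[fit@summary$parameter == parameter, ]
  if (nrow(row) == 0L) stop("unknown parameter: ", parameter)
  unlist(row[, c("mean", "sd", "q2.5", "q97.5")])
}

#' @rdname posteriorSummary
#' @export
dicOf <- function(fit) fit@dic

#' @rdname posteriorSummary
#' @export
hsSummary <- function(fit) fit@hs

#' Rank Bayesian model variants by DIC
#'
#' Smaller DIC is preferred; ties are broken by variant name so the order is
#' stable. All fits must come from the same data (checked via a data
#' fingerprint recorded at fit time).
#'
#' @param fits list of \linkS4class{HickoryFit} objects.
#' @return data.frame: variant, DIC, deltaDIC (relative to the best).
#' @export
compareModels <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, TRUE, "HickoryFit")))
  fps <- lapply(fits, function(f) f@settings$fingerprint)
  if (length(unique(vapply(fps, paste, "", collapse = "/"))) != 1L)
    stop("fits were made on different datasets")
  tab <- data.frame(variant = vapply(fits, function(f) f@variant, ""),
                    DIC = vapply(fits, function(f) f@dic, 0))
  tab <- tab[order(tab$DIC, tab$variant), , drop = FALSE]
  tab$deltaDIC <- tab$DIC - tab$DIC[1L]
  rownames(tab) <- NULL
  tab
}
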