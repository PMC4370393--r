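#' @include accessors.R
NULL

# Per-population band-frequency matrix (pops x loci) plus per-(pop,locus)
# non-missing counts; the workhorse behind most estimators.
popBandFreq <- function(x) {
  calls <- SummarizedExperiment::assay(x, "calls")  # loci x individuals
  pop <- factor(populations(x), levels = populationNames(x))
  pres <- calls; pres[is.na(pres)] <- 0L
  seen <- !is.na(calls)
  ones <- t(rowsum(t(pres), pop))          # loci x pops: counts of 1s
  tot <- t(rowsum(t(seen + 0L), pop))      # loci x pops: non-missing counts
  list(freq = t(ones) / t(tot), n = t(tot),
       pops = levels(pop), loci = rownames(calls))
}

#' Band frequency at a locus
#'
#' Proportion of non-missing calls equal to 1 — the observable primitive of
#' dominant-marker data.
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param locus locus id or index; \code{NULL} returns all loci.
#' @param scope \code{"all"} pools every individual, \code{"population"}
#'   returns a population-by-locus matrix.
#' @return numeric vector (scope "all") or matrix (scope "population").
#' @export
setMethod("bandFrequency", "BandMatrix",
  function(x, locus = NULL, scope = c("all", "population")) {
    scope <- match.arg(scope)
    calls <- SummarizedExperiment::assay(x, "calls")
    if (!is.null(locus)) calls <- calls[locus, , drop = FALSE]
    if (scope == "all") {
      n <- rowSums(!is.na(calls))
      if (any(n == 0L))
        stop("locus with no scored calls: ",
             paste(rownames(calls)[n == 0L], collapse = ", "))
      out <- rowSums(calls, na.rm = TRUE) / n
    } else {
      pb <- popBandFreq(x)
      f <- pb$freq
      if (!is.null(locus)) f <- f[, locus, drop = FALSE]
      if (anyNA(f))
        stop("some population x locus cells have no scored calls")
      out <- f
    }
    out
  })

#' Null-allele frequency from a band frequency
#'
#' Under Hardy-Weinberg equilibrium band absence occurs only in null
#' homozygotes, so the null-allele frequency is the square root of the
#' band-absence frequency: \eqn{q = \sqrt{1 - f_b}}, \eqn{p = 1 - q}. This
#' square-root estimator is the standard dominant-marker allele-frequency
#' estimate.
#'
#' @param band_freq band frequency in [0, 1].
#' @return q, the null (recessive) allele frequency.
#' @export
nullAlleleFreq <- function(band_freq) {
  stopifnot(all(band_freq >= 0 & band_freq <= 1))
  sqrt(1 - band_freq)
}

#' Polymorphic information content of a dominant locus
#'
#' \eqn{PIC = 1 - p^2 - q^2 = 2pq} on the allele frequencies estimated from
#' the band frequency; maximal at 0.5 when \eqn{q = 0.5}, i.e. at band
#' frequency 0.75.
#'
#' @param band_freq band frequency in [0, 1].
#' @return PIC value in [0, 0.5].
#' @examples
#' picDominant(0.75)  # 0.5, the maximum
#' @export
picDominant <- function(band_freq) {
  q <- nullAlleleFreq(band_freq)
  p <- 1 - q
  1 - p^2 - q^2
}

#' Marker index of a primer
#'
#' \eqn{MI = \overline{PIC} \times} number of polymorphic loci, the usual
#' summary of how much information one primer contributes.
#'
#' @param mean_pic mean PIC over the primer's loci.
#' @param n_polymorphic number of polymorphic loci (EMR).
#' @return MI, the exact product (no rounding).
#' @export
markerIndex <- function(mean_pic, n_polymorphic) {
  stopifnot(all(n_polymorphic >= 0))
  mean_pic * n_polymorphic
}

#' Shannon entropy of a band (two-state)
#'
#' \eqn{H' = -p \ln p - (1-p) \ln(1-p)} on the band presence/absence states,
#' with \eqn{0 \ln 0 \equiv 0}; bounded by \eqn{\ln 2} and symmetric about
#' p = 0.5.
#'
#' @param band_freq band frequency in [0, 1].
#' @return entropy in nats.
#' @export
shannonBand <- function(band_freq) {
  stopifnot(all(band_freq >= 0 & band_freq <= 1))
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  -xlx(band_freq) - xlx(1 - band_freq)
}

#' Per-primer marker informativeness report
#'
#' One row per primer with band counts, polymorphism, mean PIC, marker index
#' and mean Shannon entropy, plus an \code{"average"} row of unweighted
#' means over primers. A locus is polymorphic when its pooled band frequency
#' lies strictly inside (0, 1); with \code{criterion} set to 0.95 or 0.99
#' the rarer-state frequency must additionally exceed 1 - criterion.
#' Percent-polymorphic values are reported truncated (not rounded) to one
#' decimal, the convention of the classic dominant-marker reports this table
#' mirrors.
#'
#' @param x a \linkS4class{BandMatrix} with a primer panel attached (or
#'   \code{panel} given).
#' @param panel optional named character vector locus -> primer, overriding
#'   the panel stored in \code{x}.
#' @param criterion polymorphism criterion: 1 (strict, default), 0.99 or
#'   0.95.
#' @return data.frame: primer, n_bands, n_polymorphic, percent_polymorphic,
#'   mean_pic, mi, mean_shannon.
#' @export
setMethod("primerReport", "BandMatrix",
  function(x, panel = NULL, criterion = 1) {
    if (is.null(panel)) panel <- primerOf(x)
    if (is.null(panel)) stop("no primer panel available")
    if (!all(lociIds(x) %in% names(panel)))
      stop("every locus must belong to a primer")
    panel <- panel[lociIds(x)]
    fb <- bandFrequency(x)
    poly <- fb > 0 & fb < 1
    if (criterion < 1)
      poly <- poly & (pmin(fb, 1 - fb) > 1 - criterion)
    pic <- picDominant(fb)
    hp <- shannonBand(fb)
    primers <- unique(panel)
    rows <- lapply(primers, function(pr) {
      i <- panel == pr
      if (!any(i)) stop("empty primer group: ", pr)
      data.frame(primer = pr, n_bands = sum(i), n_polymorphic = sum(poly[i]),
                 percent_polymorphic = trunc1(100 * sum(poly[i]) / sum(i)),
                 mean_pic = mean(pic[i]),
                 mi = markerIndex(mean(pic[i]), sum(poly[i])),
                 mean_shannon = mean(hp[i]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    avg <- data.frame(primer = "average", n_bands = mean(out$n_bands),
                      n_polymorphic = mean(out$n_polymorphic),
                      percent_polymorphic = trunc1(mean(out$percent_polymorphic)),
                      mean_pic = mean(out$mean_pic), mi = mean(out$mi),
                      mean_shannon = mean(out$mean_shannon),
                      stringsAsFactors = FALSE)
    rbind(out, avg)
  })

# truncate (not round) to one decimal; the reporting convention of the
# percent-polymorphic column (95.45 -> 95.4).
trunc1 <- function(x) trunc(x * 10) / 10

#' Percent of polymorphic loci, report-style
#'
#' @param n_polymorphic,n_total counts.
#' @return percentage truncated to one decimal (e.g. 176/180 -> 97.7).
#' @export
percentPolymorphic <- function(n_polymorphic, n_total)
  trunc1(100 * n_polymorphic / n_total)
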