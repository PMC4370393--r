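#' @include informativeness.R
NULL

#' Per-locus diversity from the null-allele frequency
#'
#' For a dominant biallelic locus with null-allele frequency \eqn{q} (and
#' \eqn{p = 1 - q}): Nei's gene diversity \eqn{h = 1 - p^2 - q^2}, effective
#' number of alleles \eqn{N_e = 1/(p^2 + q^2) = 1/(1 - h)}, and Shannon's
#' information index \eqn{I = -p \ln p - q \ln q}.
#'
#' @param q null-allele frequency in [0, 1] (vectorised).
#' @return data.frame with columns \code{h}, \code{Ne}, \code{I}.
#' @export
locusDiversity <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  p <- 1 - q
  h <- 1 - p^2 - q^2
  xlx <- function(z) ifelse(z > 0, z * log(z), 0)
  data.frame(h = h, Ne = 1 / (1 - h), I = -xlx(p) - xlx(q))
}

#' Observed number of alleles at a dominant locus
#'
#' 2 when both band states are seen (0 < band frequency < 1), otherwise 1.
#'
#' @param band_freq band frequency in [0, 1].
#' @return integer 1 or 2 (vectorised).
#' @export
observedAlleles <- function(band_freq) {
  stopifnot(all(band_freq >= 0 & band_freq <= 1))
  ifelse(band_freq > 0 & band_freq < 1, 2L, 1L)
}

#' Band-state expected heterozygosity with small-sample correction
#'
#' Unbiased gene diversity computed on the band states themselves (haploid
#' coding): \eqn{\frac{n}{n-1}\,(1 - f_b^2 - (1-f_b)^2)}. Because it works
#' on phenotype states rather than the underlying alleles it dominates the
#' allele-based \eqn{h} at every polymorphic locus.
#'
#' @param band_freq band frequency in [0, 1].
#' @param n sample size (>= 2).
#' @return He on band states.
#' @export
expectedHetBand <- function(band_freq, n) {
  if (any(n < 2)) stop("sample size must be at least 2")
  (n / (n - 1)) * (1 - band_freq^2 - (1 - band_freq)^2)
}

#' Within-population diversity report
#'
#' Per-population means over all loci of: observed and effective allele
#' numbers, Nei's gene diversity h, Shannon's I (all on allele frequencies
#' estimated by the square-root rule) and the band-state expected
#' heterozygosity. Loci monomorphic within a population contribute zeros to
#' the means (they are not dropped). The \code{"Mean"} row is the unweighted
#' mean over populations and the \code{"Species"} row repeats the analysis
#' with every individual pooled into one population.
#'
#' @param x a \linkS4class{BandMatrix} with >= 2 individuals per population.
#' @return data.frame: population, n, Na, Ne, h, I, He_band.
#' @export
setMethod("populationDiversity", "BandMatrix", function(x) {
  pop <- populations(x)
  sizes <- table(pop)
  if (any(sizes < 2L))
    stop("populations with < 2 individuals: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  pb <- popBandFreq(x)
  oneRow <- function(label, fb, n) {
    q <- nullAlleleFreq(fb)
    ld <- locusDiversity(q)
    data.frame(population = label, n = n,
               Na = mean(observedAlleles(fb)), Ne = mean(ld$Ne),
               h = mean(ld$h), I = mean(ld$I),
               He_band = mean(expectedHetBand(fb, n)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(pb$pops), function(k)
    oneRow(pb$pops[k], pb$freq[k, ], as.integer(sizes[pb$pops[k]])))
  out <- do.call(rbind, rows)
  meanRow <- data.frame(population = "Mean", n = mean(out$n),
                        Na = mean(out$Na), Ne = mean(out$Ne),
                        h = mean(out$h), I = mean(out$I),
                        He_band = mean(out$He_band), stringsAsFactors = FALSE)
  fbAll <- bandFrequency(x)
  species <- oneRow("Species", fbAll, nIndividuals(x))
  rbind(out, meanRow, species)
})
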