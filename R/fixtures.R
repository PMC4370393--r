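#' @include io.R
NULL

fixturePath <- function(name)
  system.file("extdata", name, package = "dompop", mustWork = TRUE)

#' Sampling sites of the reference ISSR study
#'
#' The eight wild \emph{Lilium regale} populations sampled along the Minjiang
#' river system, with coordinates parsed from degrees-minutes-seconds to
#' signed decimal degrees, altitudes (m) and sample sizes.
#'
#' @return data.frame: population, site, valley, longitude, latitude,
#'   altitude_m, n_sampled.
#' @export
regaleSites <- function() {
  s <- read.table(fixturePath("lregale_sites.csv"), sep = ",", header = TRUE,
                  stringsAsFactors = FALSE)
  data.frame(population = s$population, site = s$site, valley = s$valley,
             longitude = parseDMS(s$longitude_dms),
             latitude = parseDMS(s$latitude_dms),
             altitude_m = s$altitude_m, n_sampled = s$n_sampled,
             stringsAsFactors = FALSE)
}

#' Primer panel summary of the reference ISSR study
#'
#' Published per-primer marker statistics for the ten ISSR primers: number of
#' bands, number polymorphic (EMR), percent polymorphic, mean PIC, marker
#' index and Shannon entropy.
#'
#' @return data.frame with one row per primer.
#' @export
regalePrimerTable <- function()
  read.table(fixturePath("lregale_primers.csv"), sep = ",", header = TRUE,
             stringsAsFactors = FALSE)

#' Published pairwise distances of the reference ISSR study
#'
#' The 8x8 table holding Nei's unbiased genetic distance below the diagonal
#' and pairwise Fst above it, split into two symmetric
#' \linkS4class{LabeledDistance} objects.
#'
#' @return list with elements \code{neiD} (units "nei-D") and \code{fst}
#'   (units "fst").
#' @export
regaleDistances <- function() {
  raw <- as.matrix(read.table(fixturePath("lregale_distances.csv"),
                              sep = ",", header = TRUE, row.names = 1L,
                              check.names = FALSE))
  lower <- raw; lower[upper.tri(lower)] <- 0; lower[is.na(lower)] <- 0
  upper <- raw; upper[lower.tri(upper)] <- 0; upper[is.na(upper)] <- 0
  list(neiD = LabeledDistance(lower + t(lower), units = "nei-D"),
       fst = LabeledDistance(upper + t(upper), units = "fst"))
}
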