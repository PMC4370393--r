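#' @import methods
#' @importFrom stats var sd quantile rbeta rbinom rgamma runif rnorm
#'   fisher.test setNames cor
#' @importFrom utils read.table write.table combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' BandMatrix: dominant marker presence/absence calls
#'
#' A container for a binary band matrix from dominant markers (ISSR, RAPD,
#' AFLP). Extends \linkS4class{SummarizedExperiment}: the \code{"calls"} assay
#' holds loci in rows and individuals in columns with values 0 (band absent),
#' 1 (band present) or \code{NA} (missing). \code{colData} carries the
#' population label of each individual; \code{rowData} optionally carries the
#' primer that amplified each locus.
#'
#' Under the dominant-marker model a band is present whenever the individual
#' carries at least one copy of the amplifiable ("dominant") allele, and
#' absent only in null homozygotes, so genotypes are never observed directly.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{BandMatrix}} (constructor), \code{\link{bandCalls}},
#'   \code{\link{populations}}, \code{\link{simulateDominant}}
#' @name BandMatrix-class
#' @aliases BandMatrix-class
#' @exportClass BandMatrix
setClass("BandMatrix", contains = "SummarizedExperiment")

setValidity("BandMatrix", function(object) {
  msg <- character()
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    bad <- !(m %in% c(0, 1)) & !is.na(m)
    if (any(bad))
      msg <- c(msg, "calls must be 0, 1 or NA")
  }
  if (!("population" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData column 'population' is required")
  else if (anyNA(SummarizedExperiment::colData(object)$population))
    msg <- c(msg, "every individual needs a population label")
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 individuals are required")
  if (nrow(object) < 1L)
    msg <- c(msg, "at least 1 locus is required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BandMatrix
#'
#' @param calls numeric matrix of band calls, \emph{individuals in rows and
#'   loci in columns} (the orientation of scoring sheets and of the text
#'   format read by \code{\link{readBandMatrix}}). Values must be 0, 1 or
#'   \code{NA}. Row and column names become individual and locus ids;
#'   defaults are generated when absent.
#' @param population character or factor of population labels, one per
#'   individual.
#' @param primer optional character vector assigning each locus to the primer
#'   that produced it.
#' @return a \linkS4class{BandMatrix}.
#' @examples
#' m <- BandMatrix(matrix(c(1, 0, 1, 1), 2, 2), population = c("A", "A"))
#' nIndividuals(m)
#' @export
BandMatrix <- function(calls, population, primer = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (length(population) != nrow(calls))
    stop("'population' must have one entry per individual (row of 'calls')")
  storage.mode(calls) <- "integer"
  cd <- S4Vectors::DataFrame(population = as.character(population),
                             row.names = rownames(calls))
  rd <- if (is.null(primer)) S4Vectors::DataFrame(row.names = colnames(calls))
        else {
          if (length(primer) != ncol(calls))
            stop("'primer' must have one entry per locus (column of 'calls')")
          S4Vectors::DataFrame(primer = as.character(primer),
                               row.names = colnames(calls))
        }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = t(calls)), colData = cd, rowData = rd)
  new("BandMatrix", se)
}

#' Labelled distance matrix
#'
#' Symmetric matrix of pairwise distances with a units tag saying what kind
#' of distance it holds (\code{"nei-D"}, \code{"fst"}, \code{"km"},
#' \code{"band-mismatch"}, ...). Validity enforces symmetry (within 1e-12), a
#' zero diagonal and no missing entries.
#'
#' @slot values symmetric numeric matrix with dimnames.
#' @slot units single character tag.
#' @name LabeledDistance-class
#' @exportClass LabeledDistance
setClass("LabeledDistance",
         representation(values = "matrix", units = "character"))

setValidity("LabeledDistance", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (anyNA(v)) msg <- c(msg, "no missing entries allowed")
  else {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  }
  if (is.null(rownames(v))) msg <- c(msg, "labels (dimnames) are required")
  if (length(object@units) != 1L) msg <- c(msg, "units must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledDistance
#'
#' @param values square symmetric numeric matrix (dimnames used as labels; a
#'   \code{labels} argument may supply them instead).
#' @param units character tag describing the distance.
#' @param labels optional labels overriding the dimnames.
#' @return a \linkS4class{LabeledDistance}.
#' @export
LabeledDistance <- function(values, units = "distance", labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  values <- (values + t(values)) / 2  # kill representational asymmetry
  diag(values) <- 0
  new("LabeledDistance", values = values, units = units)
}

#' UPGMA tree
#'
#' Rooted ultrametric tree from average-linkage agglomeration, stored in
#' hclust-style encoding: row i of \code{merge} gives the two clusters joined
#' at step i (negative = leaf index, positive = earlier step) and
#' \code{height[i]} the height of that node (half the merge distance).
#'
#' @slot merge integer matrix (n-1 x 2).
#' @slot height numeric node heights, non-decreasing along merges.
#' @slot labels leaf labels.
#' @name UpgmaTree-class
#' @exportClass UpgmaTree
setClass("UpgmaTree",
         representation(merge = "matrix", height = "numeric",
                        labels = "character"))

setValidity("UpgmaTree", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "merge must have n-1 rows")
  if (length(object@height) != n - 1L) msg <- c(msg, "height must have n-1 entries")
  if (is.unsorted(object@height)) msg <- c(msg, "heights must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Parameters behind a simulated dominant-marker dataset: ancestral
#' dominant-allele frequencies per locus, the differentiation (theta) and
#' inbreeding (f) used, and the realized per-population allele frequencies.
#'
#' @slot pi numeric, ancestral dominant-allele frequency per locus.
#' @slot theta differentiation used to disperse population frequencies.
#' @slot f within-population inbreeding coefficient.
#' @slot popFreq matrix (population x locus) of realized dominant-allele
#'   frequencies.
#' @slot seed integer seed used.
#' @name SimulationTruth-class
#' @exportClass SimulationTruth
setClass("SimulationTruth",
         representation(pi = "numeric", theta = "numeric", f = "numeric",
                        popFreq = "matrix", seed = "integer"))

#' AMOVA result
#'
#' One-level analysis of molecular variance: sums of squared deviations,
#' variance components, percentages and the Phi-st statistic with its
#' permutation p-value.
#'
#' @slot ssd named numeric: among, within, total.
#' @slot df named numeric degrees of freedom.
#' @slot sigma2 named numeric variance components (among, within).
#' @slot percent named numeric percentages of variance.
#' @slot phiST numeric Phi-st (NA when total SSD is zero).
#' @slot pValue permutation p-value (NA when no permutations requested).
#' @slot nPerm number of permutations.
#' @slot seed seed used for the permutations.
#' @name AmovaResult-class
#' @exportClass AmovaResult
setClass("AmovaResult",
         representation(ssd = "numeric", df = "numeric", sigma2 = "numeric",
                        percent = "numeric", phiST = "numeric",
                        pValue = "numeric", nPerm = "integer",
                        seed = "integer"))

#' Bayesian hierarchical fit for dominant markers
#'
#' Posterior summaries from the hierarchical beta model for dominant data
#' (panmictic heterozygosity h_s per population, differentiation thetaI and
#' thetaB, inbreeding f) plus the DIC and the MCMC settings used.
#'
#' @slot variant one of "full", "f0", "theta0", "ffree".
#' @slot summary data.frame: parameter, mean, sd, q2.5, q97.5.
#' @slot hs data.frame of per-population panmictic heterozygosity summaries.
#' @slot dic numeric DIC (Spiegelhalter decomposition).
#' @slot deviance named numeric: Dbar, Dhat, pD.
#' @slot chains list of retained chains (thetaI, thetaB, f).
#' @slot settings list: burnin, samples, thin, seed, data fingerprint.
#' @name HickoryFit-class
#' @exportClass HickoryFit
setClass("HickoryFit",
         representation(variant = "character", summary = "data.frame",
                        hs = "data.frame", dic = "numeric",
                        deviance = "numeric", chains = "list",
                        settings = "list"))

#' Admixture-model clustering result
#'
#' One run of the Gibbs sampler for the admixture model on haploid-coded
#' bands: posterior-mean ancestry fractions Q (individuals x K, rows sum to
#' 1) and the estimated log probability of the data for the run.
#'
#' @slot K number of clusters.
#' @slot Q numeric matrix of ancestry fractions.
#' @slot lnP estimated ln P(data | K) for this run.
#' @slot settings list: burnin, reps, seed.
#' @name AdmixtureResult-class
#' @exportClass AdmixtureResult
setClass("AdmixtureResult",
         representation(K = "integer", Q = "matrix", lnP = "numeric",
                        settings = "list"))

#' Evanno delta-K table
#'
#' Per-K summaries of replicate log-probabilities and the second-order
#' delta-K statistic; delta-K is undefined at the smallest and largest K.
#'
#' @slot table data.frame: K, n_reps, mean_lnP, sd_lnP, deltaK.
#' @slot optimalK interior K maximising delta-K.
#' @name EvannoTable-class
#' @exportClass EvannoTable
setClass("EvannoTable",
         representation(table = "data.frame", optimalK = "integer"))
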