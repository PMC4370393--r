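#' @include AllClasses.R
NULL

#' @export
setGeneric("bandCalls", function(x) standardGeneric("bandCalls"))
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))
#' @export
setGeneric("primerOf", function(x) standardGeneric("primerOf"))
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))
#' @export
setGeneric("distUnits", function(x) standardGeneric("distUnits"))
#' @export
setGeneric("bandFrequency",
           function(x, locus = NULL, scope = c("all", "population"))
             standardGeneric("bandFrequency"))
#' @export
setGeneric("primerReport", function(x, ...) standardGeneric("primerReport"))
#' @export
setGeneric("populationDiversity",
           function(x, ...) standardGeneric("populationDiversity"))
#' @export
setGeneric("gstDominant", function(x, ...) standardGeneric("gstDominant"))
#' @export
setGeneric("amova", function(x, ...) standardGeneric("amova"))
#' @export
setGeneric("pairwiseFst", function(x, ...) standardGeneric("pairwiseFst"))
#' @export
setGeneric("ldScreen", function(x, ...) standardGeneric("ldScreen"))
#' @export
setGeneric("neiDistance", function(x, ...) standardGeneric("neiDistance"))
#' @export
setGeneric("fitHickory",
           function(x, variant = c("full", "f0", "theta0", "ffree"),
                    burn_in = 50000L, samples = 250000L, thin = 50L, seed)
             standardGeneric("fitHickory"))
#' @export
setGeneric("fitAdmixture",
           function(x, K, burn_in = 10000L, reps = 100000L, seed,
                    n_replicates = 1L)
             standardGeneric("fitAdmixture"))
#' @export
setGeneric("writeBandMatrix",
           function(x, path, ...) standardGeneric("writeBandMatrix"))
#' @export
setGeneric("writeStructure",
           function(x, path, ...) standardGeneric("writeStructure"))
#' @export
setGeneric("upgma", function(x, ...) standardGeneric("upgma"))
#' @export
setGeneric("pcoa", function(x, ...) standardGeneric("pcoa"))
#' @export
setGeneric("newick", function(x, ...) standardGeneric("newick"))
#' @export
setGeneric("cutTree", function(x, k) standardGeneric("cutTree"))
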