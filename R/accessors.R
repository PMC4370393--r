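#' @include AllGenerics.R
NULL

#' Accessors for BandMatrix
#'
#' \code{bandCalls} returns the call matrix in the user-facing orientation,
#' individuals in rows and loci in columns (the transpose of the stored
#' assay). \code{populations} returns the per-individual population labels,
#' \code{populationNames} the sorted unique labels, and \code{primerOf} the
#' per-locus primer assignment (or \code{NULL} when no panel was attached).
#'
#' @param x a \linkS4class{BandMatrix}.
#' @return see description.
#' @name BandMatrix-accessors
#' @aliases bandCalls populations populationNames primerOf nIndividuals
#'   nLoci individualIds lociIds
NULL

#' @rdname BandMatrix-accessors
#' @export
setMethod("bandCalls", "BandMatrix", function(x)
  t(SummarizedExperiment::assay(x, "calls")))

#' @rdname BandMatrix-accessors
#' @export
setMethod("populations", "BandMatrix", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$population),
           colnames(x)))

#' @rdname BandMatrix-accessors
#' @export
setMethod("populationNames", "BandMatrix", function(x)
  sort(unique(as.character(SummarizedExperiment::colData(x)$population))))

#' @rdname BandMatrix-accessors
#' @export
setMethod("primerOf", "BandMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!("primer" %in% colnames(rd))) return(NULL)
  setNames(as.character(rd$primer), rownames(x))
})

#' @rdname BandMatrix-accessors
#' @export
setMethod("nIndividuals", "BandMatrix", function(x) ncol(x))

#' @rdname BandMatrix-accessors
#' @export
setMethod("nLoci", "BandMatrix", function(x) nrow(x))

#' @rdname BandMatrix-accessors
#' @export
setMethod("individualIds", "BandMatrix", function(x) colnames(x))

#' @rdname BandMatrix-accessors
#' @export
setMethod("lociIds", "BandMatrix", function(x) rownames(x))

#' Subset a BandMatrix to selected populations
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param pops character vector of population labels to keep.
#' @return a \linkS4class{BandMatrix} with only the selected individuals.
#' @export
subsetPopulations <- function(x, pops) {
  stopifnot(is(x, "BandMatrix"))
  keep <- populations(x) %in% pops
  if (!any(keep)) stop("no individuals in the requested populations")
  x[, keep]
}

setMethod("show", "BandMatrix", function(object) {
  pops <- table(populations(object))
  cat("BandMatrix: ", ncol(object), " individuals x ", nrow(object),
      " loci (", sum(is.na(SummarizedExperiment::assay(object, "calls"))),
      " missing calls)\n", sep = "")
  cat("populations:",
      paste0(names(pops), " (", as.integer(pops), ")", collapse = ", "),
      "\n")
  pr <- primerOf(object)
  if (!is.null(pr))
    cat("primer panel:", length(unique(pr)), "primers\n")
})

#' Accessors for LabeledDistance
#'
#' @param x a \linkS4class{LabeledDistance}.
#' @return \code{distValues}: the symmetric matrix; \code{distUnits}: the
#'   units tag; \code{labels}: the item labels.
#' @name LabeledDistance-accessors
#' @aliases distValues distUnits
NULL

#' @rdname LabeledDistance-accessors
#' @export
setMethod("distValues", "LabeledDistance", function(x) x@values)

#' @rdname LabeledDistance-accessors
#' @export
setMethod("distUnits", "LabeledDistance", function(x) x@units)

#' @export
setMethod("labels", "LabeledDistance", function(object, ...)
  rownames(object@values))

#' @export
setMethod("dim", "LabeledDistance", function(x) dim(x@values))

#' @export
as.matrix.LabeledDistance <- function(x, ...) x@values

#' @export
as.dist.LabeledDistance <- function(m, ...) stats::as.dist(m@values)

setMethod("show", "LabeledDistance", function(object) {
  cat("LabeledDistance [", object@units, "] over ", nrow(object@values),
      " items: ", paste(utils::head(labels(object), 6), collapse = ", "),
      if (nrow(object@values) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "UpgmaTree", function(object) {
  cat("UpgmaTree with", length(object@labels), "leaves;",
      "root height", format(max(object@height), digits = 4), "\n")
  cat(newick(object), "\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: ", ncol(object@popFreq), " loci x ",
      nrow(object@popFreq), " populations; theta=", object@theta,
      ", f=", object@f, ", seed=", object@seed, "\n", sep = "")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (one level)\n")
  tab <- data.frame(
    df = object@df[c("among", "within")],
    SSD = object@ssd[c("among", "within")],
    sigma2 = object@sigma2[c("among", "within")],
    percent = object@percent[c("among", "within")],
    row.names = c("Among populations", "Within populations"))
  print(tab)
  cat("Phi-ST =", format(object@phiST, digits = 4))
  if (!is.na(object@pValue))
    cat("  (p =", format(object@pValue, digits = 4),
        "from", object@nPerm, "permutations)")
  cat("\n")
})

setMethod("show", "HickoryFit", function(object) {
  cat("Bayesian dominant-marker fit, variant '", object@variant, "'\n",
      sep = "")
  print(object@summary, row.names = FALSE, digits = 4)
  cat("DIC =", format(object@dic, digits = 6),
      " (Dbar =", format(object@deviance[["Dbar"]], digits = 6),
      ", pD =", format(object@deviance[["pD"]], digits = 4), ")\n")
})

setMethod("show", "AdmixtureResult", function(object) {
  cat("AdmixtureResult: K =", object@K, ", n =", nrow(object@Q),
      "individuals, lnP =", format(object@lnP, digits = 6), "\n")
})

setMethod("show", "EvannoTable", function(object) {
  print(object@table, row.names = FALSE, digits = 5)
  cat("optimal K =", object@optimalK, "\n")
})

#' Evanno table accessors
#'
#' @param x an \linkS4class{EvannoTable}.
#' @return \code{deltaKTable}: the per-K data.frame; \code{optimalK}: the
#'   delta-K-maximising interior K.
#' @export
deltaKTable <- function(x) x@table

#' @rdname deltaKTable
#' @export
optimalK <- function(x) x@optimalK
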