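#' @include accessors.R
NULL

#' Read a band matrix from delimited text
#'
#' The expected dialect is a header line \code{id,pop,<locus1>,...} followed
#' by one row per individual; calls are 0/1 with \code{missing_code} marking
#' missing scores.
#'
#' @param path file to read.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param missing_code token that encodes a missing call (default "-9").
#' @param verbose log the dimensions read.
#' @return a \linkS4class{BandMatrix}.
#' @export
readBandMatrix <- function(path, dialect = c("csv", "tsv"),
                           missing_code = "-9", verbose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  if (ncol(raw) < 3L)
    stop("expected columns id, pop and at least one locus")
  ids <- raw[[1L]]
  pop <- raw[[2L]]
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  loci <- colnames(raw)[-(1:2)]
  if (anyDuplicated(loci))
    stop("duplicate locus ids in header")
  calls <- as.matrix(raw[, -(1:2), drop = FALSE])
  calls[calls == missing_code] <- NA
  ok <- is.na(calls) | calls == "0" | calls == "1"
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary token '%s' at row %d (individual %s), locus %s",
                 calls[bad[1L], bad[2L]], bad[1L], ids[bad[1L]],
                 loci[bad[2L]]))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(ids, loci)
  if (verbose)
    message("read ", nrow(calls), " individuals x ", ncol(calls), " loci")
  BandMatrix(calls, population = pop)
}

#' Write a band matrix as delimited text
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param path output file.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param missing_code token written for missing calls.
#' @return invisibly, the path.
#' @export
setMethod("writeBandMatrix", "BandMatrix",
  function(x, path, dialect = c("csv", "tsv"), missing_code = "-9") {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "csv") "," else "\t"
    m <- bandCalls(x)
    out <- cbind(id = individualIds(x), pop = unname(populations(x)),
                 `storage.mode<-`(m, "character"))
    out[is.na(out)] <- missing_code
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
  })

#' Export a band matrix in STRUCTURE format
#'
#' Each band is coded as one haploid biallelic locus: one line per
#' individual holding its id, an integer population index and one 0/1 allele
#' column per locus, with missing calls written as -9. This haploid coding is
#' the standard way of passing dominant data to admixture-model clustering.
#'
#' @param x a \linkS4class{BandMatrix}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
setMethod("writeStructure", "BandMatrix", function(x, path) {
  m <- bandCalls(x)
  popIdx <- as.integer(factor(populations(x),
                              levels = unique(unname(populations(x)))))
  m[is.na(m)] <- -9L
  lines <- paste(individualIds(x), popIdx,
                 apply(m, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
})

#' Read a STRUCTURE-format haploid export
#'
#' Inverse of \code{\link{writeStructure}} for the dialect it writes
#' (populations recoded as \code{pop<index>} unless a label map is given).
#'
#' @param path file to read.
#' @param popLabels optional character vector mapping population indices back
#'   to labels.
#' @param lociIds optional locus names.
#' @return a \linkS4class{BandMatrix}.
#' @export
readStructure <- function(path, popLabels = NULL, lociIds = NULL) {
  rows <- strsplit(trimws(readLines(path)), "[ \t]+")
  rows <- rows[lengths(rows) > 0L]
  ids <- vapply(rows, `[[`, "", 1L)
  idx <- as.integer(vapply(rows, `[[`, "", 2L))
  calls <- do.call(rbind, lapply(rows, function(r) as.integer(r[-(1:2)])))
  calls[calls == -9L] <- NA_integer_
  pop <- if (is.null(popLabels)) paste0("pop", idx) else popLabels[idx]
  rownames(calls) <- ids
  colnames(calls) <- if (is.null(lociIds))
    paste0("L", seq_len(ncol(calls))) else lociIds
  BandMatrix(calls, population = pop)
}

#' Parse a degrees-minutes-seconds coordinate
#'
#' Accepts strings like \code{"103°45′31″E"} (also plain quotes \code{' "}),
#' returning signed decimal degrees: deg + min/60 + sec/3600, negated for
#' the S and W hemispheres.
#'
#' @param x DMS string, hemisphere letter either embedded as a suffix or
#'   passed separately.
#' @param hemisphere optional "N", "S", "E" or "W"; overrides any suffix.
#' @return decimal degrees (vectorised over \code{x}).
#' @examples
#' parseDMS("103°45′31″E")  # 103.7586
#' @export
parseDMS <- function(x, hemisphere = NULL) {
  one <- function(s, hemi) {
    s <- gsub("\\s+", "", s)
    mm <- regmatches(s, regexec(
      "^([0-9]+)[°d]([0-9]+)[′'m]([0-9]+(?:\\.[0-9]+)?)[″\"s]?([NSEW]?)$",
      s))[[1L]]
    if (length(mm) == 0L) stop("malformed DMS string: '", s, "'")
    deg <- as.numeric(mm[2L]); mi <- as.numeric(mm[3L]); se <- as.numeric(mm[4L])
    if (mi >= 60 || se >= 60) stop("minutes and seconds must be in [0,60): ", s)
    h <- if (!is.null(hemi) && nzchar(hemi)) hemi else mm[5L]
    val <- deg + mi / 60 + se / 3600
    if (h %in% c("S", "W")) val <- -val
    else if (!(h %in% c("N", "E", "")))
      stop("unknown hemisphere: ", h)
    val
  }
  if (is.null(hemisphere)) hemisphere <- rep("", length(x))
  mapply(one, x, hemisphere, USE.NAMES = FALSE)
}

#' Format decimal degrees as DMS
#'
#' Inverse of \code{\link{parseDMS}} (up to integer seconds).
#'
#' @param x decimal degrees.
#' @param axis \code{"lat"} or \code{"lon"}, selects N/S vs E/W.
#' @return character DMS strings.
#' @export
formatDMS <- function(x, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  hemi <- ifelse(x >= 0, if (axis == "lat") "N" else "E",
                 if (axis == "lat") "S" else "W")
  a <- abs(x)
  deg <- floor(a)
  mi <- floor((a - deg) * 60)
  se <- round(((a - deg) * 60 - mi) * 60)
  # carry rounding overflow
  mi <- mi + (se >= 60); se <- se %% 60
  deg <- deg + (mi >= 60); mi <- mi %% 60
  sprintf("%d°%d′%d″%s", deg, mi, se, hemi)
}
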