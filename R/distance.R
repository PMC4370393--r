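#' @include differentiation.R
NULL

#' Nei's (1978) unbiased genetic identity/distance from allele frequencies
#'
#' For biallelic dominant loci with null-allele frequencies \code{qX},
#' \code{qY} and sample sizes \code{nX}, \code{nY}: the within-population
#' identities use the small-sample-unbiased form
#' \eqn{(2n \sum_i p_i^2 - 1)/(2n - 1)} per locus, the between-population
#' identity is \eqn{\sum_i p_{Xi} p_{Yi}}, and
#' \eqn{D_s = -\ln(\bar J_{XY} / \sqrt{\bar J_X \bar J_Y})} with means taken
#' over loci.
#'
#' @param qX,qY numeric vectors of per-locus null-allele frequencies.
#' @param nX,nY sample sizes (scalars or per-locus vectors, >= 2).
#' @return the unbiased distance Ds (symmetric in X and Y).
#' @export
neiUnbiasedD <- function(qX, qY, nX, nY) {
  stopifnot(length(qX) == length(qY), all(nX >= 2), all(nY >= 2))
  pX <- 1 - qX; pY <- 1 - qY
  jX <- (2 * nX * (pX^2 + qX^2) - 1) / (2 * nX - 1)
  jY <- (2 * nY * (pY^2 + qY^2) - 1) / (2 * nY - 1)
  jXY <- pX * pY + qX * qY
  num <- mean(jXY); den <- sqrt(mean(jX) * mean(jY))
  if (num <= 0 || den <= 0)
    stop("zero genetic identity: distance undefined (log of zero)")
  -log(num / den)
}

#' Nei's unbiased genetic distance between populations
#'
#' Applies \code{\link{neiUnbiasedD}} to every pair of populations, with
#' allele frequencies estimated by the square-root rule and per-locus sample
#' sizes taken from the non-missing call counts.
#'
#' @param x a \linkS4class{BandMatrix} with >= 2 individuals per population.
#' @return a \linkS4class{LabeledDistance} with units \code{"nei-D"}.
#' @export
setMethod("neiDistance", "BandMatrix", function(x) {
  pb <- popBandFreq(x)
  if (any(pb$n < 2))
    stop("every population needs >= 2 scored individuals at every locus")
  q <- nullAlleleFreq(pb$freq)
  k <- length(pb$pops)
  d <- matrix(0, k, k, dimnames = list(pb$pops, pb$pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    d[i, j] <- d[j, i] <- neiUnbiasedD(q[i, ], q[j, ],
                                       pb$n[i, ], pb$n[j, ])
  LabeledDistance(d, units = "nei-D")
})

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: at every step the closest pair of clusters
#' is merged, with cluster-to-cluster distance the arithmetic mean of all
#' cross-pairs of original distances and node height half the merge
#' distance (so the tree is ultrametric). Exact ties are broken by the
#' lexicographically smallest pair of cluster labels, a cluster being
#' labelled by its alphabetically first leaf.
#'
#' @param x a \linkS4class{LabeledDistance} or symmetric matrix with
#'   dimnames.
#' @return an \linkS4class{UpgmaTree}.
#' @export
setMethod("upgma", "LabeledDistance", function(x) upgmaCore(x@values))

#' @rdname upgma-LabeledDistance-method
#' @export
setMethod("upgma", "matrix", function(x) upgmaCore(x))

upgmaCore <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  id <- -seq_len(n)                 # hclust codes of active clusters
  size <- rep(1L, n)
  rep_lab <- labs                   # representative (alphabetically first) leaf
  cur <- d                          # current cluster-cluster mean distances
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(id)
    best <- NULL; bestD <- Inf
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      dd <- cur[a, b]
      pair <- sort(c(rep_lab[a], rep_lab[b]))
      if (dd < bestD - 1e-15) {
        bestD <- dd; best <- c(a, b); bestPair <- pair
      } else if (abs(dd - bestD) <= 1e-15) {
        if (pair[1L] < bestPair[1L] ||
            (pair[1L] == bestPair[1L] && pair[2L] < bestPair[2L])) {
          bestD <- min(bestD, dd); best <- c(a, b); bestPair <- pair
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    # child with the alphabetically first representative goes left
    merge[s, ] <- if (rep_lab[a] <= rep_lab[b]) c(id[a], id[b])
                  else c(id[b], id[a])
    height[s] <- bestD / 2
    # Lance-Williams update gives the mean over all original cross-pairs
    newRow <- (size[a] * cur[a, ] + size[b] * cur[b, ]) /
              (size[a] + size[b])
    keep <- setdiff(seq_len(m), c(a, b))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newRow[keep]),
                 c(newRow[keep], 0))
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(a, b)]))
    size <- c(size[keep], size[a] + size[b])
    id <- c(id[keep], s)
  }
  new("UpgmaTree", merge = merge, height = height, labels = labs)
}

#' Newick string of an UPGMA tree
#'
#' Branch lengths are differences of node heights (leaves sit at height 0).
#'
#' @param x an \linkS4class{UpgmaTree}.
#' @param digits significant digits for branch lengths.
#' @return a Newick string terminated by ";".
#' @export
setMethod("newick", "UpgmaTree", function(x, digits = 10) {
  fmt <- function(v) format(v, digits = digits, trim = TRUE,
                            scientific = FALSE)
  build <- function(node) {
    if (node < 0L) list(str = x@labels[-node], h = 0)
    else {
      l <- build(x@merge[node, 1L]); r <- build(x@merge[node, 2L])
      h <- x@height[node]
      list(str = paste0("(", l$str, ":", fmt(h - l$h), ",",
                        r$str, ":", fmt(h - r$h), ")"), h = h)
    }
  }
  paste0(build(nrow(x@merge))$str, ";")
})

#' Cut an UPGMA tree into k groups
#'
#' Removes the last k-1 merges (the highest ones, since heights are
#' non-decreasing) and reports the resulting leaf partition.
#'
#' @param x an \linkS4class{UpgmaTree}.
#' @param k number of groups (1 <= k <= number of leaves).
#' @return named integer vector of group memberships (groups numbered in
#'   order of each group's first leaf).
#' @export
setMethod("cutTree", "UpgmaTree", function(x, k) {
  n <- length(x@labels)
  stopifnot(k >= 1L, k <= n)
  memb <- -seq_len(n)              # cluster code per leaf
  nKeep <- n - k
  for (s in seq_len(nKeep)) {
    memb[memb %in% x@merge[s, ]] <- s
  }
  grp <- as.integer(factor(memb, levels = unique(memb)))
  setNames(grp, x@labels)
})

#' Principal coordinates analysis
#'
#' Classic metric ordination: Gower double-centering of \eqn{-d^2/2}
#' followed by an eigendecomposition. Axes are ordered by eigenvalue;
#' percent variance is computed over the positive eigenvalues only (negative
#' ones, which arise for non-Euclidean distances, are reported but excluded
#' from the percentages).
#'
#' @param x a \linkS4class{LabeledDistance} or symmetric matrix.
#' @param n_axes number of axes to keep (default: all positive).
#' @return list: \code{coordinates} (items x axes, scaled by sqrt of
#'   eigenvalue), \code{eigenvalues}, \code{percent} (per retained axis).
#' @export
setMethod("pcoa", "LabeledDistance",
          function(x, n_axes = NULL) pcoaCore(x@values, n_axes))

#' @rdname pcoa-LabeledDistance-method
#' @export
setMethod("pcoa", "matrix", function(x, n_axes = NULL) pcoaCore(x, n_axes))

pcoaCore <- function(d, n_axes = NULL) {
  n <- nrow(d)
  if (all(d == 0)) stop("all-zero distance matrix")
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  pos <- lam > max(lam) * 1e-9
  keep <- which(pos)
  if (!is.null(n_axes)) keep <- keep[seq_len(min(n_axes, length(keep)))]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lam[keep]), length(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(keep))
  list(coordinates = coords, eigenvalues = lam,
       percent = 100 * lam[keep] / sum(lam[pos]))
}

#' Great-circle distances between sampling sites
#'
#' Haversine distances (mean Earth radius 6371.0088 km) between sites given
#' in decimal degrees.
#'
#' @param sites data.frame with columns \code{population}, \code{longitude},
#'   \code{latitude} (as returned by \code{\link{regaleSites}}).
#' @return a \linkS4class{LabeledDistance} in km.
#' @export
geographicDistance <- function(sites) {
  stopifnot(all(c("population", "longitude", "latitude") %in% names(sites)),
            all(abs(sites$latitude) <= 90),
            all(abs(sites$longitude) <= 180))
  n <- nrow(sites)
  d <- matrix(0, n, n, dimnames = list(sites$population, sites$population))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- geosphere::distHaversine(
      c(sites$longitude[i], sites$latitude[i]),
      c(sites$longitude[j], sites$latitude[j]), r = 6371008.8) / 1000
  LabeledDistance(d, units = "km")
}

allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower-triangle entries, with significance
#' from jointly permuting rows and columns of the second matrix. The default
#' two-sided p-value counts permutations with \eqn{|r| \ge |r_{obs}|}
#' (observed included); for small problems (n! <= 5040, i.e. n <= 7) the
#' null is enumerated exhaustively instead of sampled.
#'
#' @param d1,d2 \linkS4class{LabeledDistance} objects (or matrices) over the
#'   same labels in the same order.
#' @param n_perm number of random permutations when not exhaustive.
#' @param seed integer seed (required unless exhaustive).
#' @param exhaustive \code{"auto"} (enumerate when n <= 7), \code{TRUE} or
#'   \code{FALSE}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list: \code{r}, \code{p}, \code{n_perm} (permutations evaluated),
#'   \code{exhaustive}.
#' @export
mantelTest <- function(d1, d2, n_perm = 999L, seed = NULL,
                       exhaustive = "auto",
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m1 <- if (is(d1, "LabeledDistance")) d1@values else as.matrix(d1)
  m2 <- if (is(d2, "LabeledDistance")) d2@values else as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("matrices must have the same dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrices must share labels in the same order")
  n <- nrow(m1)
  if (n < 3L) stop("need at least 3 items")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (sd(v1) == 0 || sd(m2[lt]) == 0)
    stop("zero variance in a distance triangle; correlation undefined")
  rOf <- function(perm) cor(v1, m2[perm, perm][lt])
  rObs <- rOf(seq_len(n))
  doExh <- identical(exhaustive, TRUE) ||
    (identical(exhaustive, "auto") && factorial(n) <= 5040)
  cmp <- switch(alternative,
                two.sided = function(r) abs(r) >= abs(rObs) - 1e-12,
                greater = function(r) r >= rObs - 1e-12,
                less = function(r) r <= rObs + 1e-12)
  if (doExh) {
    rs <- vapply(allPerms(n), rOf, numeric(1))
    p <- mean(cmp(rs))
    nEval <- length(rs)
  } else {
    if (is.null(seed)) stop("a seed is required for sampled permutations")
    set.seed(as.integer(seed))
    hits <- 1L
    for (b in seq_len(n_perm)) if (cmp(rOf(sample(n)))) hits <- hits + 1L
    p <- hits / (n_perm + 1L)
    nEval <- as.integer(n_perm)
  }
  list(r = rObs, p = p, n_perm = nEval, exhaustive = doExh)
}
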