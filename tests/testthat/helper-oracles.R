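# Independent oracles and small fixture builders used across the suite.

# random band matrix with guaranteed per-population structure
randBandMatrix <- function(n_pops, n_per, n_loci, seed) {
  set.seed(seed)
  calls <- matrix(rbinom(n_pops * n_per * n_loci, 1, runif(n_loci, 0.2, 0.8)),
                  n_pops * n_per, n_loci, byrow = FALSE)
  BandMatrix(calls, population = rep(paste0("P", seq_len(n_pops)),
                                     each = n_per))
}

# Brute-force one-level AMOVA: direct double loops over the SSD and
# expected-mean-square formulas, no shared code with the package.
amovaOracle <- function(m) {
  calls <- bandCalls(m)
  pop <- populations(m)
  N <- nrow(calls)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    d2[i, j] <- sum((calls[i, ok] - calls[j, ok])^2)
  }
  ssdT <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) ssdT <- ssdT + d2[i, j]
  ssdT <- ssdT / (2 * N)
  ssdW <- 0
  for (g in unique(pop)) {
    idx <- which(pop == g)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    ssdW <- ssdW + s / (2 * length(idx))
  }
  ssdA <- ssdT - ssdW
  G <- length(unique(pop))
  ng <- as.numeric(table(pop))
  dfA <- G - 1
  dfW <- N - G
  n0 <- (N - sum(ng^2) / N) / dfA
  sW <- ssdW / dfW
  sA <- (ssdA / dfA - sW) / n0
  list(ssdA = ssdA, ssdW = ssdW, ssdT = ssdT, sA = sA, sW = sW,
       phi = sA / (sA + sW))
}

# Brute-force UPGMA: keeps explicit member lists and recomputes every
# cluster-to-cluster mean from the original matrix at every step; ties by
# lexicographically smallest label pair.
upgmaOracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- list()
  repeat {
    m <- length(clusters)
    if (m == 1L) break
    best <- NULL; bestD <- Inf; bestPair <- NULL
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      A <- clusters[[a]]; B <- clusters[[b]]
      dd <- mean(d[A, B])
      pr <- sort(c(min(A), min(B)))
      better <- dd < bestD - 1e-15 ||
        (abs(dd - bestD) <= 1e-15 &&
           (pr[1] < bestPair[1] ||
              (pr[1] == bestPair[1] && pr[2] < bestPair[2])))
      if (is.null(best) || better) {
        best <- c(a, b); bestD <- dd; bestPair <- pr
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights[[length(heights) + 1L]] <-
      list(members = merged, h = bestD / 2)
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# leaf -> root-path heights from an UpgmaTree, for comparing with the oracle
upgmaMergeSets <- function(tree) {
  n <- length(tree@labels)
  members <- vector("list", n - 1L)
  getm <- function(code) if (code < 0) tree@labels[-code]
                         else members[[code]]
  for (s in seq_len(n - 1L))
    members[[s]] <- sort(c(getm(tree@merge[s, 1L]),
                           getm(tree@merge[s, 2L])))
  lapply(seq_len(n - 1L), function(s)
    list(members = members[[s]], h = tree@height[s]))
}

# plain haversine, written independently of the package
haversineOracle <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(a))
}

# exhaustive Mantel p-value by explicit permutation enumeration (uses
# base gtools-free recursion distinct from the package's)
mantelOracle <- function(m1, m2) {
  n <- nrow(m1)
  lt <- lower.tri(m1)
  r0 <- cor(m1[lt], m2[lt])
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rs <- sapply(perms(seq_len(n)), function(p) {
    mp <- m2[p, p]
    cor(m1[lt], mp[lt])
  })
  list(r = r0, p = mean(abs(rs) >= abs(r0) - 1e-12))
}
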