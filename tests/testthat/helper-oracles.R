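# Independent brute-force oracles, written at definition level (explicit
# loops, no shared code with the package implementations they check).

oracleClusterDescriptors <- function(points, labels) {
  ks <- sort(unique(labels))
  sizes <- dispersion <- extent <- numeric(length(ks))
  mu <- c(mean(points[, 1]), mean(points[, 2]))
  bgss <- 0
  for (i in seq_along(ks)) {
    pts <- points[labels == ks[i], , drop = FALSE]
    sizes[i] <- nrow(pts)
    ck <- c(mean(pts[, 1]), mean(pts[, 2]))
    dd <- numeric(nrow(pts))
    for (j in seq_len(nrow(pts)))
      dd[j] <- sqrt(sum((pts[j, ] - ck)^2))
    dispersion[i] <- mean(dd)
    ext <- 0
    if (nrow(pts) > 1L)
      for (a in 1:(nrow(pts) - 1L)) for (b in (a + 1L):nrow(pts))
        ext <- max(ext, sqrt(sum((pts[a, ] - pts[b, ])^2)))
    extent[i] <- ext
    bgss <- bgss + nrow(pts) * sum((ck - mu)^2)
  }
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  c(K = length(ks), clusterSizeMean = mean(sizes),
    clusterSizeSd = psd(sizes), dispersionMean = mean(dispersion),
    dispersionSd = psd(dispersion), extentMean = mean(extent),
    extentSd = psd(extent), bgss = bgss)
}

oracleValidityIndices <- function(points, labels, eps = 1e-12) {
  ks <- sort(unique(labels))
  K <- length(ks); n <- nrow(points)
  wgssK <- sizes <- delta <- numeric(K)
  cents <- matrix(0, K, 2L)
  for (i in seq_along(ks)) {
    pts <- points[labels == ks[i], , drop = FALSE]
    sizes[i] <- nrow(pts)
    cents[i, ] <- c(mean(pts[, 1]), mean(pts[, 2]))
    s <- 0; sd1 <- 0
    for (j in seq_len(nrow(pts))) {
      d2 <- sum((pts[j, ] - cents[i, ])^2)
      s <- s + d2
      sd1 <- sd1 + sqrt(d2)
    }
    wgssK[i] <- s
    delta[i] <- sd1 / nrow(pts)
  }
  wgss <- sum(wgssK)
  mu <- c(mean(points[, 1]), mean(points[, 2]))
  bgss <- 0
  for (i in seq_len(K)) bgss <- bgss + sizes[i] * sum((cents[i, ] - mu)^2)
  ballHall <- mean(wgssK / sizes)
  br <- 0
  for (i in seq_len(K)) br <- br + sizes[i] * log(max(wgssK[i] / sizes[i], eps))
  db <- 0
  for (i in seq_len(K)) {
    best <- -Inf
    for (l in seq_len(K)) if (l != i) {
      v <- (delta[i] + delta[l]) / sqrt(sum((cents[i, ] - cents[l, ])^2))
      if (v > best) best <- v
    }
    db <- db + best
  }
  db <- db / K
  ch <- if (wgss > 0) (bgss / (K - 1)) / (wgss / (n - K)) else Inf
  allD <- numeric(0); within <- numeric(0)
  for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    d <- sqrt(sum((points[a, ] - points[b, ])^2))
    allD <- c(allD, d)
    if (labels[a] == labels[b]) within <- c(within, d)
  }
  nW <- length(within)
  if (nW == 0L) {
    cidx <- 0
  } else {
    srt <- sort(allD)
    sMin <- sum(srt[1:nW])
    sMax <- sum(srt[(length(srt) - nW + 1L):length(srt)])
    sW <- sum(within)
    cidx <- if (sMax > sMin) (sW - sMin) / (sMax - sMin) else 0
  }
  c(ballHall = ballHall, banfeldRaftery = br,
    logSSRatio = if (wgss > 0) log(bgss / wgss) else Inf,
    daviesBouldin = db, calinskiHarabasz = ch, cIndex = cidx)
}

oracleDegreeFeatures <- function(n, edges) {
  deg <- integer(n)
  for (e in seq_len(nrow(edges))) {
    deg[edges[e, 1]] <- deg[edges[e, 1]] + 1L
    deg[edges[e, 2]] <- deg[edges[e, 2]] + 1L
  }
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  tab <- table(deg) / n
  entropy <- -sum(tab * log2(tab))
  ## assortativity: Pearson correlation of endpoint degrees over directed
  ## edge pairs
  if (nrow(edges) > 0L) {
    di <- c(deg[edges[, 1]], deg[edges[, 2]])
    dj <- c(deg[edges[, 2]], deg[edges[, 1]])
    assort <- suppressWarnings(cor(di, dj))
    if (is.na(assort)) assort <- NA_real_
  } else assort <- NA_real_
  ## local clustering: fraction of neighbour pairs that are connected;
  ## degree < 2 counts 0
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(edges))) {
    adj[edges[e, 1], edges[e, 2]] <- TRUE
    adj[edges[e, 2], edges[e, 1]] <- TRUE
  }
  lc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (length(nb) < 2L) { lc[v] <- 0; next }
    links <- 0L; pairs <- 0L
    for (a in 1:(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
      pairs <- pairs + 1L
      if (adj[nb[a], nb[b]]) links <- links + 1L
    }
    lc[v] <- links / pairs
  }
  c(degMean = mean(deg), degSd = psd(deg), degMax = max(deg),
    fracIsolated = mean(deg == 0L), degEntropy = entropy,
    assortativity = assort, localClustering = mean(lc))
}

oracleRadiusEdges <- function(points, r) {
  n <- nrow(points)
  out <- matrix(integer(), 0L, 2L)
  for (a in 1:(n - 1L)) for (b in (a + 1L):n)
    if (sqrt(sum((points[a, ] - points[b, ])^2)) <= r)
      out <- rbind(out, c(a, b))
  out
}

## AUC by explicit concordant/discordant pair counting (ties count 1/2)
oracleAuc <- function(scores, truth) {
  pos <- which(truth == 1); neg <- which(truth == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

## Exact two-sided Mann-Whitney p over all choose(n, na) arrangements:
## P(|U - na nb / 2| >= |U_obs - na nb / 2|), mid-ranks.
oracleMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  Uobs <- sum(rk[1:na]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combos <- combn(na + nb, na)
  hits <- 0L
  for (i in seq_len(ncol(combos))) {
    U <- sum(rk[combos[, i]]) - na * (na + 1) / 2
    if (abs(U - mu) >= abs(Uobs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combos)
}

## Brute-force sliding-window inference geometry: which 40x40 cells are
## positive when a window scores 1 iff it contains the point (row, col).
oracleOracleCells <- function(h, w, objRow, objCol, patch = 151L,
                              stride = 40L, cell = 40L) {
  mask <- matrix(0, h, w)
  for (r0 in seq(0L, h - patch, by = stride))
    for (c0 in seq(0L, w - patch, by = stride)) {
      hit <- objRow >= r0 && objRow <= r0 + patch - 1L &&
        objCol >= c0 && objCol <= c0 + patch - 1L
      if (hit)
        mask[(r0 + 1L):(r0 + patch), (c0 + 1L):(c0 + patch)] <- 1
    }
  nr <- ceiling(h / cell); nc <- ceiling(w / cell)
  cells <- matrix(integer(), 0L, 2L)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- ((i - 1L) * cell + 1L):min(i * cell, h)
    cc <- ((j - 1L) * cell + 1L):min(j * cell, w)
    if (max(mask[rr, cc]) >= 0.5)
      cells <- rbind(cells, c(i - 1L, j - 1L))
  }
  cells
}
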