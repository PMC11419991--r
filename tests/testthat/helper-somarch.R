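# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (pair counting, explicit double loops, exhaustive
# enumeration) and never call the implementation they check.

# k Gaussian blobs around the rows of `centers`
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers); p <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# four well-separated blobs at the corners of a square
blob_square <- function(n_per = 30, sep = 8, sd = 1, seed = 1) {
  make_blobs(n_per, sep * rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
             sd = sd, seed = seed)
}

# ARI by direct pair counting over all C(n,2) object pairs
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa) s10 <- s10 + 1
    else if (sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  tot <- choose(n, 2)
  e <- (s11 + s10) * (s11 + s01) / tot
  m <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(m - e) < 1e-12) return(as.numeric(s11 == m))
  (s11 - e) / (m - e)
}

# AMI with MI from an explicit double loop and E[MI] via dhyper()
brute_ami <- function(a, b) {
  n <- length(a)
  ct <- table(a, b)
  ai <- rowSums(ct); bj <- colSums(ct)
  ha <- -sum((ai / n) * log(ai / n))
  hb <- -sum((bj / n) * log(bj / n))
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    for (nij in seq_len(min(ai[i], bj[j]))) {
      pr <- stats::dhyper(nij, ai[i], n - ai[i], bj[j])
      if (pr > 0) emi <- emi + pr * nij / n * log(n * nij / (ai[i] * bj[j]))
    }
  }
  ha <- unname(ha); hb <- unname(hb); mi <- unname(mi); emi <- unname(emi)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) {
    same <- all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
    return(as.numeric(same))
  }
  (mi - emi) / denom
}

# naive average-linkage agglomeration on a dissimilarity matrix, k-cut
brute_average_linkage <- function(d, k) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  labels
}

# consensus matrix by explicit triple loop
brute_consensus <- function(labels) {
  n <- ncol(labels); r <- nrow(labels)
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    cnt <- 0
    for (s in 1:r) if (labels[s, i] == labels[s, j]) cnt <- cnt + 1
    m[i, j] <- cnt / r
  }
  m
}

# small synthetic study used by several files
tiny_study <- function(seed = 1, n_subjects = 30, n_runs = 2, n_nodes = 16,
                       noise_sd = 0.2, run_consistency = 0.9) {
  simulate_study(synth_config(n_subjects = n_subjects, n_runs = n_runs,
                              n_nodes = n_nodes, noise_sd = noise_sd,
                              run_consistency = run_consistency,
                              seed = seed))
}

# rank-q planted dataset: orthonormal loadings, unit noise
planted_rank <- function(n, p, sds, seed) {
  set.seed(seed)
  v <- qr.Q(qr(matrix(rnorm(p * length(sds)), p)))[, seq_along(sds)]
  z <- matrix(rnorm(n * length(sds)), n)
  z %*% (t(v) * sds) + matrix(rnorm(n * p), n, p)
}
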