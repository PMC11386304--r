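# Independent brute-force oracles. These deliberately use naive loops and
# explicit enumeration, sharing no code with the package implementations
# they check.

# Per-site pairwise difference/comparison counts by enumerating every pair
# of called allele copies.
oraclePiSite <- function(siteCalls) {
  alleles <- integer(0)
  for (g in siteCalls) {
    if (is.na(g)) next
    alleles <- c(alleles, switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  }
  n <- length(alleles)
  diffs <- 0L; comps <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      comps <- comps + 1L
      if (alleles[i] != alleles[j]) diffs <- diffs + 1L
    }
  }
  c(diffs = diffs, comps = comps)
}

oraclePiMatrix <- function(gt) {
  out <- t(vapply(seq_len(nrow(gt)),
                  function(i) oraclePiSite(gt[i, ]), c(diffs = 0, comps = 0)))
  colSums(out)
}

# Brute-force sliding-window ROH caller: materialises every window and
# every support ratio.
oracleRoh <- function(calls, pos, cfg) {
  n <- length(calls)
  w <- cfg@windowSnps
  maxHet <- floor(cfg@maxHetFracWindow * w)
  maxMiss <- floor(cfg@maxMissFracWindow * w)
  nw <- n - w + 1L
  verdict <- if (nw >= 1) {
    vapply(seq_len(nw), function(s) {
      win <- calls[s:(s + w - 1L)]
      sum(win == 1L, na.rm = TRUE) <= maxHet &&
        sum(is.na(win)) <= maxMiss
    }, logical(1))
  } else logical(0)
  included <- logical(n)
  if (nw >= 1) {
    for (i in seq_len(n)) {
      cov <- intersect(seq(i - w + 1L, i), seq_len(nw))
      if (length(cov))
        included[i] <- mean(verdict[cov]) >= cfg@supportThreshold
    }
  }
  runs <- list()
  cur <- integer(0)
  for (i in seq_len(n)) {
    if (included[i]) {
      if (length(cur) && pos[i] - pos[cur[length(cur)]] > cfg@maxGapBp) {
        runs[[length(runs) + 1L]] <- cur
        cur <- integer(0)
      }
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  keep <- list()
  for (r in runs) {
    len <- pos[r[length(r)]] - pos[r[1]] + 1
    if (length(r) >= cfg@minSnpsPerRun && len >= cfg@minLengthBp &&
        len / length(r) <= cfg@minDensityBpPerSnp)
      keep[[length(keep) + 1L]] <- data.frame(
        start = pos[r[1]], end = pos[r[length(r)]],
        n_snps = length(r), length_bp = len)
  }
  if (!length(keep))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  do.call(rbind, keep)
}

# Random scaffold generator for oracle-equivalence checks: homozygous
# blocks planted in a heterozygous background, plus missing calls and a
# sprinkle of sparse regions so that every run filter gets exercised.
randomRohScaffold <- function(nSnps = 2000, spacingBp = 1000) {
  gaps <- sample(c(rep(spacingBp, nSnps - 1)), nSnps - 1)
  sparse <- sample(nSnps - 1, round(0.02 * nSnps))
  gaps[sparse] <- sample(c(5e4, 2e5), length(sparse), replace = TRUE)
  pos <- cumsum(c(1, gaps))
  calls <- sample(c(0L, 1L, 2L), nSnps, replace = TRUE,
                  prob = c(0.35, 0.4, 0.25))
  nBlocks <- sample(0:3, 1)
  for (b in seq_len(nBlocks)) {
    st <- sample(nSnps - 50, 1)
    len <- sample(c(60, 120, 300, 700), 1)
    idx <- st:min(nSnps, st + len - 1)
    calls[idx] <- sample(c(0L, 2L), length(idx), replace = TRUE)
    err <- idx[runif(length(idx)) < 0.01]
    calls[err] <- 1L
  }
  mis <- runif(nSnps) < 0.03
  calls[mis] <- NA
  list(calls = calls, pos = pos)
}
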