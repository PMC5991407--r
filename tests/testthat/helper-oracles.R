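# Independent oracles and fixture builders used across the test files.

# Exhaustive O(n^2) seasonal-peak counter, coded independently of the
# package implementation: plateau-collapsed neighbor comparison, brute-force
# topographic prominence, then greedy height-first separation pruning.
brute_force_peak_count <- function(curve, min_ndvi = 0.3,
                                   min_prominence = 0.1,
                                   min_separation = 3) {
  n <- length(curve)
  pos <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && curve[j + 1L] == curve[i]) j <- j + 1L
    if (i > 1L && j < n && curve[i - 1L] < curve[i] && curve[j + 1L] < curve[i])
      pos <- c(pos, i + (j - i) %/% 2L)
    i <- j + 1L
  }
  if (length(pos) == 0) return(0L)
  prom <- sapply(pos, function(p) {
    h <- curve[p]
    left <- h
    for (q in rev(seq_len(p - 1L))) {
      if (curve[q] > h) break
      left <- min(left, curve[q])
    }
    right <- h
    for (q in seq(p + 1L, n)) {
      if (q > n) break
      if (curve[q] > h) break
      right <- min(right, curve[q])
    }
    h - max(left, right)
  })
  ok <- curve[pos] >= min_ndvi - 1e-12 & prom >= min_prominence - 1e-12
  pos <- pos[ok]
  if (length(pos) <= 1) return(length(pos))
  h <- curve[pos]
  ord <- order(-h, pos)
  kept <- integer(0)
  for (q in ord) {
    good <- TRUE
    for (r in kept) if (abs(pos[q] - pos[r]) < min_separation) good <- FALSE
    if (good) kept <- c(kept, q)
  }
  length(kept)
}

# Deterministic multi-year series from a phenology, optional annual offsets.
make_series <- function(id = "T1", area = 500, years = 2001:2013,
                        params = phenology_params(), offsets = 0) {
  offsets <- rep_len(offsets, length(years))
  M <- t(vapply(seq_along(years),
                function(j) seasonal_curve(params, years[j]) + offsets[j],
                numeric(23)))
  M[M > 1] <- 1; M[M < -0.2] <- -0.2
  ndvi_series(id, area, years, M)
}

# Two well-separated Gaussian clusters in 16 dimensions with labels.
separable_clusters <- function(n, gap = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, -1L), length.out = n)
  x <- matrix(rnorm(n * 16), n, 16)
  x[y == 1L, 1] <- x[y == 1L, 1] + gap
  colnames(x) <- paste0("f", 1:16)
  list(x = x, y = y)
}
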