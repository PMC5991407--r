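#' Detect seasonal NDVI peaks within one year
#'
#' Finds the crop-cycle peaks of a 23-composite annual NDVI curve: local
#' maxima (plateaus counted once, at the plateau center) that clear an
#' absolute NDVI floor, a topographic-prominence threshold, and a minimum
#' mutual separation. Prominence is measured against the higher of the two
#' bases reached before the curve rises above the peak on either side (the
#' usual 1-D topographic definition). When two candidate peaks fall closer
#' than `min_separation` composites, the higher one wins (ties go to the
#' earlier composite).
#'
#' @param curve numeric vector of 23 gap-free NDVI values.
#' @param min_ndvi absolute NDVI floor a peak must reach (bare soil and
#'   off-season noise sit below ~0.3).
#' @param min_prominence minimum prominence in NDVI units.
#' @param min_separation minimum distance between retained peaks, in
#'   composites (3 composites = 48 days, shorter than any crop cycle).
#' @return data.frame with columns `position`, `height`, `prominence`, one
#'   row per retained peak, ordered by position.
#' @export
find_seasonal_peaks <- function(curve, min_ndvi = 0.3, min_prominence = 0.1,
                                min_separation = 3) {
  if (anyNA(curve)) stop("peak detection requires a gap-free curve")
  n <- length(curve)
  r <- rle(curve)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  pos <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
        pos <- c(pos, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  if (length(pos) == 0)
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  height <- curve[pos]
  prominence <- vapply(seq_along(pos), function(q) {
    i <- pos[q]; h <- height[q]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && curve[j] <= h) { lmin <- min(lmin, curve[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && curve[j] <= h) { rmin <- min(rmin, curve[j]); j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))

  keep <- height >= min_ndvi - 1e-12 & prominence >= min_prominence - 1e-12
  pos <- pos[keep]; height <- height[keep]; prominence <- prominence[keep]

  if (length(pos) > 1 && min_separation > 1) {
    ord <- order(-height, pos)
    kept <- integer(0)
    for (q in ord) {
      if (all(abs(pos[q] - pos[kept]) >= min_separation)) kept <- c(kept, q)
    }
    kept <- sort(kept)
    pos <- pos[kept]; height <- height[kept]; prominence <- prominence[kept]
  }
  data.frame(position = pos, height = height, prominence = prominence)
}

#' Annual NDVI peak frequency
#'
#' Number of crop cycles detected in one year's curve; the per-year
#' building block of the multi-cropping index.
#'
#' @inheritParams find_seasonal_peaks
#' @return integer peak count (0 for flat or low curves).
#' @export
peak_frequency <- function(curve, min_ndvi = 0.3, min_prominence = 0.1,
                           min_separation = 3) {
  nrow(find_seasonal_peaks(curve, min_ndvi, min_prominence, min_separation))
}
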