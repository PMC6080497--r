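# Intensive-transect analytics: empirical variogram of TCH along a line,
# and the weather-station precipitation agreement rate.

#' Empirical variogram of a transect
#'
#' For every unordered pair of points the squared value difference is
#' assigned to the half-open lag bin `[lo, hi)` containing the pair's
#' separation; each bin reports the mean squared difference `2*gamma`
#' (twice the classical semivariance) and its pair count. Pairs whose
#' separation falls outside all bins are dropped and counted in the
#' `"dropped_pairs"` attribute.
#'
#' @param positions Point positions along the transect, m.
#' @param values Values at the points (e.g. TCH, t/ha).
#' @param bin_edges Increasing vector of bin edges, m.
#' @return Tibble of class `variogram` with columns `h` (bin centre, m),
#'   `two_gamma` (mean squared difference; `NA` for an empty bin) and
#'   `n_pairs`.
#' @examples
#' empirical_variogram(c(0, 5, 10), c(1, 2, 4), bin_edges = c(2.5, 7.5, 12.5))
#' @export
empirical_variogram <- function(positions, values, bin_edges) {
  if (length(positions) != length(values)) {
    stop_input("`positions` and `values` must have equal length")
  }
  if (length(positions) < 2) stop_input("need at least 2 points")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_input("`bin_edges` must be strictly increasing")
  }
  n <- length(positions)
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  h <- abs(positions[ij[, 2]] - positions[ij[, 1]])
  d2 <- (values[ij[, 2]] - values[ij[, 1]])^2
  # half-open [lo, hi) bins
  bin <- findInterval(h, bin_edges, left.open = FALSE, rightmost.closed = FALSE)
  inside <- bin >= 1 & bin < length(bin_edges)
  dropped <- sum(!inside)
  n_bins <- length(bin_edges) - 1
  two_gamma <- rep(NA_real_, n_bins)
  n_pairs <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- inside & bin == b
    n_pairs[b] <- sum(sel)
    if (n_pairs[b] > 0) two_gamma[b] <- mean(d2[sel])
  }
  out <- tibble(
    h = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
    two_gamma = two_gamma,
    n_pairs = n_pairs
  )
  attr(out, "dropped_pairs") <- dropped
  class(out) <- c("variogram", class(out))
  out
}

#' TCH values for an intensive transect
#'
#' The composition used for transect variograms: the field's re-fitted
#' cane-biomass curve evaluated at the measurement day, multiplied by the
#' locally measured cane spatial densities.
#'
#' @param biomass_fit The field's `logistic_fit` for cane biomass.
#' @param t Measurement day (days since start of growth).
#' @param C_row Locally measured cane counts per row-metre.
#' @param S Mean row spacing, m.
#' @return TCH values, t/ha.
#' @export
intensive_tch <- function(biomass_fit, t, C_row, S = 1.2) {
  bm <- predict(biomass_fit, t)
  tch(bm, C_row, S)
}

#' Precipitation detection agreement between weather stations
#'
#' A station detects precipitation on a day when its daily cumulative
#' rainfall is positive. The agreement rate is the fraction of
#' station-pair-days on which the two stations' detection status matches,
#' averaged over all pairs; missing values are excluded pairwise. The
#' stricter alternative counts only days on which all stations agree.
#'
#' @param detections Matrix or data frame, days in rows, stations in
#'   columns; entries are 0/1 detections (or rainfall amounts, thresholded
#'   at > 0) with `NA` for missing.
#' @param method `"pairwise"` (default) or `"unanimity"`.
#' @return Agreement rate in `[0, 1]`.
#' @examples
#' precipitation_agreement(cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 1)))
#' @export
precipitation_agreement <- function(detections, method = c("pairwise", "unanimity")) {
  method <- match.arg(method)
  m <- as.matrix(detections)
  if (ncol(m) < 2) stop_input("need at least 2 stations")
  if (nrow(m) < 1) stop_input("need at least 1 day")
  det <- m > 0
  mode(det) <- "integer"
  if (method == "unanimity") {
    day_ok <- apply(det, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2) NA else as.integer(all(r == r[1]))
    })
    return(mean(day_ok, na.rm = TRUE))
  }
  pairs <- utils::combn(ncol(det), 2)
  rates <- apply(pairs, 2, function(p) {
    a <- det[, p[1]]; b <- det[, p[2]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean(a[ok] == b[ok])
  })
  mean(rates, na.rm = TRUE)
}
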