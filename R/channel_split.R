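# HU channel splitting: instead of normalising or clipping CT intensities,
# each Hounsfield value is expanded into window-sensitive feature channels,
# mirroring how a radiologist reads the same image under several display
# windows (air/lung, soft tissue, bone). The windows form a triangular
# partition of unity, so the mapping is continuous, differentiable almost
# everywhere, and loses no intensity information in aggregate.

#' Construct a bank of triangular HU windows
#'
#' Channel c responds with the piecewise-linear "hat" weight of the (clamped)
#' HU value relative to `centers[c]`, with support reaching exactly to the
#' adjacent centers. Responses are in \[0, 1\] and sum to 1 for every HU in
#' the domain.
#'
#' @param centers Strictly increasing HU window centers. The first/last
#'   center must coincide with the domain ends so clamping is consistent.
#' @param domain HU domain `(min, max)` to which inputs are clamped.
#' @return A `pp_window_bank` with fields `centers`, `widths` (support
#'   half-widths to the adjacent centers), `n_channels` and `domain`.
#' @export
window_bank <- function(centers, domain = c(-1024, 3071)) {
  centers <- as.numeric(centers)
  assert_that(all(diff(centers) > 0), "window centers must be strictly increasing")
  assert_that(centers[1] == domain[1] && centers[length(centers)] == domain[2],
              "first/last centers must coincide with the domain ends")
  n <- length(centers)
  widths <- cbind(left = c(NA, diff(centers)), right = c(diff(centers), NA))
  structure(list(centers = centers, widths = widths, n_channels = n,
                 domain = as.numeric(domain)), class = "pp_window_bank")
}

#' Default 11-channel window bank
#'
#' Centers are denser in the diagnostic range (lung, fat, soft tissue,
#' contrast/bone onset) and sparser toward dense bone, following the window
#' settings radiologists actually use.
#'
#' @return A [window_bank()] with 11 channels on \[-1024, 3071\] HU.
#' @export
default_bank <- function() {
  window_bank(c(-1024, -600, -200, -60, 0, 60, 150, 400, 1000, 1800, 3071))
}

#' Split an HU grid into window channels
#'
#' @param hu Numeric array (any shape) of HU values; values outside the
#'   bank's domain are clamped first.
#' @param bank A [window_bank()].
#' @return Array with a leading channel axis: dim `c(n_channels, dim(hu))`
#'   (or `c(n_channels, length(hu))` for dimensionless input). Channels sum
#'   to 1 at every voxel.
#' @export
split_channels <- function(hu, bank = default_bank()) {
  d <- dim(hu) %||% length(hu)
  v <- pmin(pmax(as.numeric(hu), bank$domain[1]), bank$domain[2])
  cen <- bank$centers
  n <- bank$n_channels
  # interval index: k such that cen[k] <= v <= cen[k+1]
  k <- findInterval(v, cen, rightmost.closed = TRUE)
  k[k >= n] <- n - 1L
  w_hi <- (v - cen[k]) / (cen[k + 1] - cen[k])
  out <- matrix(0, n, length(v))
  idx <- seq_along(v)
  out[cbind(k, idx)] <- 1 - w_hi
  out[cbind(k + 1L, idx)] <- out[cbind(k + 1L, idx)] + w_hi
  dim(out) <- c(n, d)
  out
}
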