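#' Logarithmic resolution binning
#'
#' Partitions reflections into resolution bins whose boundaries are
#' uniformly spaced in ln(d), merging under-populated slices so that
#' every bin holds at least `min_count` reflections.  Because the
#' low-resolution region of a diffraction data set is sparse, uniform
#' ln(d) spacing gives several thin low-resolution bins (each holding
#' roughly `min_count` reflections after merging) while high-resolution
#' bins may hold many more -- the sampling the bulk-solvent scale curve
#' needs, without inflating the total number of bins.
#'
#' Under-populated ln(d) slices are merged with their neighbour toward
#' higher resolution in a single descending-d sweep; a reflection whose
#' d falls exactly on a shared boundary is assigned to the
#' lower-resolution (larger-d) bin.
#'
#' @param d Positive numeric vector of resolutions in Angstrom.
#' @param min_count Minimum number of reflections per bin (default 300).
#' @param max_bins Maximum number of ln(d) slices before merging
#'   (default 30); the uniform step is widened to respect it.
#' @return Object of class `bin_partition`: `boundaries` (descending
#'   d values, length `n_bins + 1`), `bin_of` (1-based bin id per
#'   reflection), `counts`, `n_bins`.
#' @examples
#' d <- exp(runif(5000, log(1.5), log(20)))
#' bp <- log_d_bins(d, min_count = 300)
#' bp$counts
#' @export
log_d_bins <- function(d, min_count = 300, max_bins = 30) {
  d <- as.numeric(d)
  if (length(d) == 0L) stop("empty input: no reflections to bin")
  if (any(!is.finite(d)) || any(d <= 0)) stop("all d must be positive and finite")
  if (min_count < 1) stop("min_count must be >= 1")
  n <- length(d)
  dmax <- max(d)
  dmin <- min(d)
  if (n < min_count || dmax == dmin) {
    boundaries <- c(dmax, dmin)
  } else {
    n_slices <- max(1L, min(as.integer(max_bins), n %/% as.integer(min_count)))
    raw <- dmax * exp(-log(dmax / dmin) * (0:n_slices) / n_slices)
    raw[length(raw)] <- dmin   # guard against rounding past the data
    counts <- tabulate(assign_bins(d, raw), nbins = n_slices)
    # descending-d sweep: close a bin once the accumulated count reaches
    # the floor, otherwise keep absorbing the next (higher-resolution) slice
    keep <- logical(n_slices + 1L)
    keep[1L] <- TRUE
    acc <- 0L
    for (i in seq_len(n_slices)) {
      acc <- acc + counts[i]
      if (acc >= min_count && i < n_slices) {
        keep[i + 1L] <- TRUE
        acc <- 0L
      }
    }
    keep[n_slices + 1L] <- TRUE
    boundaries <- raw[keep]
    # the last (highest-resolution) bin may have come up short: merge back
    if (length(boundaries) > 2L) {
      cnt <- tabulate(assign_bins(d, boundaries),
                      nbins = length(boundaries) - 1L)
      if (cnt[length(cnt)] < min_count)
        boundaries <- boundaries[-(length(boundaries) - 1L)]
    }
  }
  bin_of <- assign_bins(d, boundaries)
  n_bins <- length(boundaries) - 1L
  structure(
    list(boundaries = boundaries, bin_of = bin_of,
         counts = tabulate(bin_of, nbins = n_bins), n_bins = n_bins),
    class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("bin_partition: %d bins over %.3g-%.3g A\n",
              x$n_bins, x$boundaries[1], x$boundaries[x$n_bins + 1]))
  tbl <- format_bin_table(x)
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Per-bin summary table
#'
#' @param partition A `bin_partition`.
#' @return data.frame with bin id, resolution range and count, mirroring
#'   the usual per-shell report layout.
#' @export
format_bin_table <- function(partition) {
  nb <- partition$n_bins
  data.frame(
    bin = seq_len(nb),
    d_max = partition$boundaries[seq_len(nb)],
    d_min = partition$boundaries[seq_len(nb) + 1L],
    count = partition$counts)
}

#' Assign reflections to resolution bins
#'
#' Boundary d values are descending; bin i spans boundaries i (large d)
#' to i+1 (small d).  A d exactly on a shared boundary goes to the
#' lower-resolution (larger-d) bin; d values outside the boundary range
#' are clamped to the nearest bin (with a message).
#'
#' @param d Numeric vector of resolutions in Angstrom.
#' @param boundaries Strictly decreasing numeric vector (length
#'   `n_bins + 1`).
#' @return Integer vector of 1-based bin ids.
#' @export
assign_bins <- function(d, boundaries) {
  nb <- length(boundaries) - 1L
  if (nb < 1L) stop("need at least two boundaries")
  if (nb > 1L && any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing")
  asc <- rev(boundaries)
  j <- findInterval(d, asc)        # asc[j] <= d < asc[j+1]
  bin <- nb + 1L - j
  out_of_range <- bin < 1L | bin > nb
  n_clamped <- sum(d < asc[1] | d > asc[length(asc)])
  if (n_clamped > 0L)
    message(sprintf("assign_bins: %d reflections outside the boundary range were clamped", n_clamped))
  pmin(pmax(bin, 1L), nb)
}

#' Equal-count binning uniform in d^-3 (comparison utility)
#'
#' The conventional scheme: boundaries uniform in d^-3, which gives
#' approximately equal reflection counts per bin but few low-resolution
#' bins.  Provided for comparison with [log_d_bins()], not as a default.
#'
#' @param d Positive numeric vector of resolutions in Angstrom.
#' @param n_bins Number of bins.
#' @return A `bin_partition`.
#' @export
d3_bins <- function(d, n_bins = 20) {
  d <- as.numeric(d)
  if (length(d) == 0L) stop("empty input: no reflections to bin")
  dmax <- max(d)
  dmin <- min(d)
  if (dmax == dmin || n_bins < 2) {
    boundaries <- c(dmax, dmin)
  } else {
    boundaries <- (seq(dmax^-3, dmin^-3, length.out = n_bins + 1L))^(-1 / 3)
    boundaries[1] <- dmax
    boundaries[n_bins + 1L] <- dmin
  }
  bin_of <- assign_bins(d, boundaries)
  nb <- length(boundaries) - 1L
  structure(
    list(boundaries = boundaries, bin_of = bin_of,
         counts = tabulate(bin_of, nbins = nb), n_bins = nb),
    class = "bin_partition")
}
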