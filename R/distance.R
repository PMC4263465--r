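#' Distance from each region to its nearest high-affinity site
#'
#' Distance is the interval-to-interval gap in bp: 0 when a region overlaps
#' or abuts a HAS, otherwise the number of bases strictly between them.
#'
#' @param regions Bound-region tibble (`chrom`, `start`, `end`; any extra
#'   columns are preserved).
#' @param has IntervalSet tibble of high-affinity sites.
#' @return `regions` with an added `has_distance` column (bp).
#' @export
nearest_has_distance <- function(regions, has) {
  if (nrow(regions) == 0) abort("No regions supplied.")
  if (nrow(has) == 0) abort("No HAS supplied.")
  d <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    qi <- which(regions$chrom == ch)
    s <- has[has$chrom == ch, ]
    if (nrow(s) == 0) {
      abort(paste0("No HAS on chromosome ", ch,
                   "; cannot compute distances there."))
    }
    d[qi] <- gap_distance(regions$start[qi], regions$end[qi],
                          s$start, s$end)
  }
  out <- regions
  out$has_distance <- d
  out
}

# Vectorized nearest-gap distance from query intervals to a set of subject
# intervals on one chromosome.  Subjects are merged first so overlapping
# annotation records cannot confuse the neighbour search.
gap_distance <- function(q_start, q_end, s_start, s_end) {
  m <- merge_intervals(s_start, s_end)
  ss <- m$start; se <- m$end
  k <- length(ss)
  idx <- findInterval(q_start, ss)      # last subject starting <= q_start
  left <- ifelse(idx >= 1, q_start - se[pmax(idx, 1)], Inf)
  right <- ifelse(idx < k, ss[pmin(idx + 1, k)] - q_end, Inf)
  pmax(0, pmin(left, right))
}

# merge overlapping/adjacent intervals (vectors, 0-based half-open)
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) <= 1) return(list(start = start, end = end))
  cummax_end <- cummax(end)
  new_grp <- c(TRUE, start[-1] > cummax_end[-length(end)])
  grp <- cumsum(new_grp)
  list(start = as.numeric(tapply(start, grp, min)),
       end = as.numeric(tapply(cummax_end, grp, max)))
}

#' Bin nearest distances into a fractional profile
#'
#' Bins are `[0, w), [w, 2w), ..., [(n-1)w, Inf)`: the last bin is
#' open-ended, so fractions always sum to 1.
#'
#' @param distances Numeric vector of distances, or a tibble carrying a
#'   `has_distance` column (as returned by [nearest_has_distance()]).
#' @param bin_width Bin width in bp (default 5000).
#' @param n_bins Number of bins (default 8; must be at least 2).
#' @param label Profile label, e.g. `"observed"` or `"random"`.
#' @return A `distance_profile` tibble: `label`, `bin`, `lower`, `upper`,
#'   `count`, `fraction`; attribute `n` is the number of sites.
#' @export
bin_fractions <- function(distances, bin_width = 5000, n_bins = 8,
                          label = "observed") {
  if (is.data.frame(distances)) {
    if (!"has_distance" %in% names(distances)) {
      abort("Data frame input must carry a `has_distance` column.")
    }
    distances <- distances$has_distance
  }
  if (length(distances) == 0) abort("Empty distance list.")
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  if (any(distances < 0)) abort("Distances must be non-negative.")
  bin <- pmin(floor(distances / bin_width) + 1, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  out <- tibble(
    label = label,
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * bin_width,
    upper = c(seq_len(n_bins - 1) * bin_width, Inf),
    count = counts,
    fraction = counts / length(distances)
  )
  structure(out, class = c("distance_profile", class(out)),
            n = length(distances))
}

#' Random-position control distance profile
#'
#' Draws `n` uniform positions on the chromosome, treats each as a
#' zero-length site, and bins their nearest-HAS distances exactly like the
#' observed profile.  Reproducible under `seed`.
#'
#' @param assembly A [genome_assembly()].
#' @param has HAS IntervalSet tibble.
#' @param chrom Chromosome to sample on.
#' @param n Number of random positions (default 10000).
#' @param seed RNG seed.
#' @inheritParams bin_fractions
#' @return A `distance_profile` tibble labelled `"random"`.
#' @export
random_control <- function(assembly, has, chrom, n = 10000, seed = 1,
                           bin_width = 5000, n_bins = 8) {
  check_assembly(assembly)
  check_chrom(assembly, chrom)
  if (n < 1) abort("`n` must be at least 1.")
  s <- has[has$chrom == chrom, ]
  if (nrow(s) == 0) abort(paste0("No HAS on chromosome ", chrom, "."))
  len <- assembly$seqlengths[[chrom]]
  pos <- withr::with_seed(seed, floor(runif(n, 0, len)))
  d <- gap_distance(pos, pos, s$start, s$end)
  prof <- bin_fractions(d, bin_width = bin_width, n_bins = n_bins,
                        label = "random")
  attr(prof, "seed") <- seed
  prof
}
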