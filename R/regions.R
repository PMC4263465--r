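#' Top-percentile cutoff of a track
#'
#' Nearest-rank rule: the cutoff is the r-th largest non-missing value,
#' r = ceiling(n * top_percent / 100).  A value crosses the cutoff iff it is
#' `>=` the cutoff, so ties at the cutoff all count as crossing.
#'
#' @param track A [genome_track()].
#' @param top_percent Percentage of values to extract (default 1.5).
#' @param scope `"genome"` (one cutoff over all chromosomes) or
#'   `"per_chromosome"` (named vector of cutoffs).
#'
#' @return A single cutoff, or a named vector for per-chromosome scope.
#' @export
threshold_top_percent <- function(track, top_percent = 1.5,
                                  scope = c("genome", "per_chromosome")) {
  check_track(track)
  scope <- match.arg(scope)
  if (top_percent <= 0 || top_percent >= 100) {
    abort("`top_percent` must be strictly between 0 and 100.")
  }
  cut_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) abort("Track has no non-missing values.")
    r <- max(1L, as.integer(ceiling(length(v) * top_percent / 100)))
    sort(v, decreasing = TRUE)[r]
  }
  if (scope == "genome") {
    cut_one(unlist(track$values, use.names = FALSE))
  } else {
    vapply(track$values, cut_one, 0)
  }
}

#' Call bound regions from a smoothed enrichment track
#'
#' Steps at or above the top-percentile cutoff are "data units".  Units
#' spaced no more than `max_gap` bp apart (gap measured between the end of
#' one unit's step and the start of the next) are chained into candidate
#' regions spanning from the first unit's start to the last unit's end.
#' Candidates shorter than `min_length` bp or containing fewer than
#' `min_units` units are discarded.  Each surviving region is scored with
#' the mean of its top five consecutive step values — the maximal-mean
#' window of 5 adjacent steps inside the region, computed on the smoothed
#' values whether or not each is above the cutoff — and the peak centre is
#' the genomic centre of that window (leftmost window on ties).
#'
#' @param track A smoothed log2-ratio [genome_track()].
#' @param top_percent,max_gap,min_length,min_units Calling parameters
#'   (defaults 1.5, 200 bp, 200 bp, 5).
#' @param scope Cutoff scope, see [threshold_top_percent()].
#' @param cutoff Optional precomputed cutoff (scalar, or named vector for
#'   per-chromosome scope); overrides `top_percent`.
#'
#' @return A tibble of class `msl_regions`: `chrom`, `start`, `end`,
#'   `name`, `score`, `peak_center`, `n_units`, sorted and disjoint, with
#'   the cutoff and parameters as attributes (see [glance.msl_regions()]).
#' @export
call_bound_regions <- function(track, top_percent = 1.5, max_gap = 200,
                               min_length = 200, min_units = 5,
                               scope = c("genome", "per_chromosome"),
                               cutoff = NULL) {
  check_track(track)
  scope <- match.arg(scope)
  if (max_gap < 0 || min_length <= 0 || min_units < 1) {
    abort("Gap, length and unit parameters must be positive.")
  }
  if (is.null(cutoff)) {
    cutoff <- threshold_top_percent(track, top_percent, scope)
  }
  step <- track$assembly$step_bp
  out <- purrr::map_dfr(track_chroms(track), function(ch) {
    v <- track$values[[ch]]
    cut <- if (scope == "genome") cutoff else cutoff[[ch]]
    units <- which(!is.na(v) & v >= cut)
    if (length(units) == 0) return(NULL)
    len <- track$assembly$seqlengths[[ch]]
    # chain units: gap between consecutive unit steps in bp
    gap <- (diff(units) - 1) * step
    grp <- cumsum(c(1L, as.integer(gap > max_gap)))
    purrr::map_dfr(split(units, grp), function(u) {
      first <- u[1]; last <- u[length(u)]
      r_start <- (first - 1) * step
      r_end <- min(last * step, len)
      if ((r_end - r_start) < min_length || length(u) < min_units) {
        return(NULL)
      }
      sc <- score_region(v, first, last, step, len)
      tibble(chrom = ch, start = r_start, end = r_end,
             score = sc$score, peak_center = sc$center,
             n_units = length(u))
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  score = numeric(), peak_center = numeric(),
                  n_units = integer())
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$name <- if (nrow(out) > 0) sprintf("region_%d", seq_len(nrow(out)))
              else character(0)
  out <- dplyr::select(out, "chrom", "start", "end", "name", "score",
                       "peak_center", "n_units")
  structure(out,
            class = c("msl_regions", class(out)),
            cutoff = cutoff,
            params = list(top_percent = top_percent, max_gap = max_gap,
                          min_length = min_length, min_units = min_units,
                          scope = scope))
}

# Best 5-consecutive-step mean within [first, last] and its genomic centre.
# Windows containing missing values are skipped; if no complete window
# exists the top five consecutive non-missing values are used instead.
score_region <- function(v, first, last, step, chrom_len, width = 5L) {
  vals <- v[first:last]
  n <- length(vals)
  if (n >= width) {
    i <- seq_len(n - width + 1)
    # exact per-window means (not a running sum) so that windows with
    # identical contents tie exactly and the leftmost wins
    means <- vapply(i, function(j) mean(vals[j:(j + width - 1)]), 0)
    if (any(!is.na(means))) {
      means[is.na(means)] <- -Inf
      j <- which.max(means)                       # leftmost maximum
      s <- first + j - 1                           # global start step
      w_start <- (s - 1) * step
      w_end <- min((s + width - 1) * step, chrom_len)
      return(list(score = means[j], center = (w_start + w_end) / 2))
    }
  }
  # fallback: 5 consecutive *values* (non-missing steps in order)
  ii <- (first:last)[!is.na(vals)]
  if (length(ii) < width) {
    ii <- rep(ii, length.out = width)  # unreachable when min_units >= 5
  }
  k <- seq_len(length(ii) - width + 1)
  means <- vapply(k, function(j) mean(v[ii[j:(j + width - 1)]]), 0)
  j <- which.max(means)
  w_start <- (ii[j] - 1) * step
  w_end <- min(ii[j + width - 1] * step, chrom_len)
  list(score = means[j], center = (w_start + w_end) / 2)
}

#' Summarise a region call
#'
#' @param x An `msl_regions` tibble from [call_bound_regions()].
#' @param ... Unused.
#' @return One-row tibble: number of regions, cutoff, total bp covered,
#'   mean score and the calling parameters.
#' @export
glance.msl_regions <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_regions = nrow(x),
    cutoff = if (length(attr(x, "cutoff")) == 1) attr(x, "cutoff") else NA_real_,
    total_bp = sum(x$end - x$start),
    mean_score = if (nrow(x) > 0) mean(x$score) else NA_real_,
    top_percent = p$top_percent, max_gap = p$max_gap,
    min_length = p$min_length, min_units = p$min_units, scope = p$scope
  )
}

#' Label expressed genes as bound or unbound by region overlap
#'
#' An expressed gene is labelled `"bound"` iff its span, extended by
#' `flank` bp on both sides, intersects any called region (half-open
#' intervals: a region ending exactly at the gene start does not overlap).
#' Other expressed genes become `"unbound"`; non-expressed genes stay
#' `"unassigned"`.
#'
#' @param genes Gene tibble (see [read_gene_annotation()]).
#' @param regions Bound-region tibble.
#' @param flank Flank in bp added to each gene span (default 0).
#' @return The gene tibble with an updated `group` column.
#' @export
genes_overlapping_regions <- function(genes, regions, flank = 0) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    any(regions$chrom == g$chrom &
          regions$start < g$end + flank &
          regions$end > g$start - flank)
  }, logical(1))
  genes$group <- dplyr::case_when(
    !genes$expressed ~ "unassigned",
    hit ~ "bound",
    TRUE ~ "unbound"
  )
  genes
}
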