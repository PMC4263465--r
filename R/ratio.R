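#' Compute a log2 ChIP/input enrichment-ratio track
#'
#' Both coverage tracks are first scaled to equal genome-wide totals (each
#' multiplied so its total over the jointly covered steps equals the mean of
#' the two totals), then the per-step log2 ratio is taken with an additive
#' pseudocount:
#' \deqn{r_i = \log_2\frac{c_i \cdot s_c + p}{x_i \cdot s_x + p}}
#' Steps missing in either track are missing in the output.
#'
#' @param chip,input Coverage [genome_track()]s on the same assembly.
#' @param pseudocount Positive value added to both scaled coverages
#'   (default 0.5); damps ratios at low coverage.
#' @param normalize Scale the tracks to equal totals first (default `TRUE`).
#'
#' @return A [genome_track()] with semantics `"log2_ratio"`.
#' @examples
#' asm <- genome_assembly(c(chr = 40), step_bp = 10)
#' chip <- genome_track(list(chr = c(2, 8, 4, 4)), asm)
#' inp <- genome_track(list(chr = c(4, 6, 4, 4)), asm)
#' tidy(compute_enrichment_ratio(chip, inp))
#' @export
compute_enrichment_ratio <- function(chip, input, pseudocount = 0.5,
                                     normalize = TRUE) {
  check_track(chip); check_track(input)
  check_same_assembly(chip, input)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  chroms <- track_chroms(chip)
  ok <- unlist(lapply(chroms, function(ch) {
    v <- chip$values[[ch]]; u <- input$values[[ch]]
    m <- !is.na(v) & !is.na(u)
    c(sum(v[m]), sum(u[m]))
  }))
  tc <- sum(ok[seq(1, length(ok), by = 2)])
  ti <- sum(ok[seq(2, length(ok), by = 2)])
  if (normalize) {
    if (tc <= 0 || ti <= 0) {
      abort("Cannot normalize: a track has no signal on the shared steps.")
    }
    target <- (tc + ti) / 2
    sc <- target / tc
    si <- target / ti
  } else {
    sc <- 1
    si <- 1
  }
  vals <- lapply(chroms, function(ch) {
    v <- chip$values[[ch]]; u <- input$values[[ch]]
    r <- log2((v * sc + pseudocount) / (u * si + pseudocount))
    r[is.na(v) | is.na(u)] <- NA_real_
    r
  })
  names(vals) <- chroms
  genome_track(vals, chip$assembly, smoothing = "raw",
               semantics = "log2_ratio")
}

#' Median-smooth a track with minimum-data-point discarding
#'
#' Each step's output is the median of the non-missing raw values in a
#' window of `window_bp` centred on the step; windows retaining fewer than
#' `min_points` values are discarded (output missing).  The two standard
#' presets pair a 500 bp window with 25 minimum points and a 2000 bp window
#' with 100.  Windows are truncated at chromosome ends, where the minimum
#' still applies, so edge steps are often discarded.  Even step-count
#' windows take the lower of the two central order statistics — a
#' deterministic tie rule that keeps the smoother monotone.
#'
#' @param track A raw [genome_track()].
#' @param window_bp Window size in bp; must be a multiple of the step size.
#' @param min_points Minimum non-missing values per window.  `NULL` uses the
#'   preset for `window_bp` (500 -> 25, 2000 -> 100).
#'
#' @return A [genome_track()] with `smoothing = window_bp`.
#' @export
median_smooth <- function(track, window_bp = 500, min_points = NULL) {
  check_track(track)
  step <- track$assembly$step_bp
  if (window_bp <= 0 || window_bp %% step != 0) {
    abort("`window_bp` must be a positive multiple of the step size.")
  }
  w <- as.integer(window_bp / step)
  if (is.null(min_points)) {
    min_points <- smoothing_preset(window_bp)$min_points
  }
  if (min_points < 1 || min_points > w) {
    abort(paste0("`min_points` must be in [1, ", w,
                 "] (window capacity in steps)."))
  }
  vals <- lapply(track$values, sliding_median, w = w,
                 min_points = as.integer(min_points))
  genome_track(vals, track$assembly, smoothing = window_bp,
               semantics = track$semantics)
}

#' Standard smoothing presets
#'
#' @param window_bp 500 or 2000.
#' @return List with `window_bp` and `min_points` (25 or 100).
#' @export
smoothing_preset <- function(window_bp) {
  if (window_bp == 500) return(list(window_bp = 500, min_points = 25))
  if (window_bp == 2000) return(list(window_bp = 2000, min_points = 100))
  abort("No preset for this window; pass `min_points` explicitly.")
}
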