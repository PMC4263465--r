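#' Fraction of repeat-masked bases in sliding windows
#'
#' For every step, the fraction of repeat-masked nucleotides in a window of
#' `window_bp` (default 200 bp) centred on that step.  Windows truncated at
#' chromosome ends use the truncated width as denominator, so values always
#' lie in [0, 1].
#'
#' @param repeats Repeat IntervalSet tibble (`chrom`, `start`, `end`);
#'   overlapping records are merged internally.
#' @param assembly A [genome_assembly()].
#' @param window_bp Window size in bp; must be a multiple of the step.
#' @return A [genome_track()] with semantics `"repeat_fraction"`.
#' @export
repeat_fraction_track <- function(repeats, assembly, window_bp = 200) {
  check_assembly(assembly)
  step <- assembly$step_bp
  if (window_bp <= 0 || window_bp %% step != 0) {
    abort("`window_bp` must be a positive multiple of the step size.")
  }
  w <- as.integer(window_bp / step)
  left <- w %/% 2
  right <- w - left - 1
  vals <- lapply(names(assembly$seqlengths), function(ch) {
    n <- n_steps(assembly, ch)
    bounds <- c(step_starts(assembly, ch), assembly$seqlengths[[ch]])
    r <- repeats[repeats$chrom == ch, ]
    if (nrow(r) == 0) {
      masked <- rep(0, n)
    } else {
      m <- merge_intervals(r$start, r$end)
      masked <- diff(cum_masked(bounds, m$start, m$end))
    }
    cm <- c(0, cumsum(masked))
    i <- seq_len(n)
    lo <- pmax(1, i - left)
    hi <- pmin(n, i + right)
    (cm[hi + 1] - cm[lo]) / (bounds[hi + 1] - bounds[lo])
  })
  names(vals) <- names(assembly$seqlengths)
  genome_track(vals, assembly, smoothing = window_bp,
               semantics = "repeat_fraction")
}

# cumulative masked bp in [0, x) for merged intervals; vectorized over x
cum_masked <- function(x, s, e) {
  cw <- c(0, cumsum(e - s))
  idx <- findInterval(x, s)
  ifelse(idx == 0, 0,
         cw[pmax(idx, 1)] +
           pmax(0, pmin(x, e[pmax(idx, 1)]) - s[pmax(idx, 1)]))
}

#' Repeat-content profile around transcription start sites
#'
#' For each gene, steps are assigned to distance bins of `bin_bp` from the
#' TSS (by default unsigned distance, pooling upstream and downstream;
#' `signed = TRUE` gives strand-oriented bins `-n_bins..-1, 1..n_bins`).
#' The gene's per-bin value is the mean repeat fraction over the bin's
#' steps; group summaries average over genes (genes are the independent
#' units) and report a normal-approximation 95% confidence interval.
#' Genes whose window runs past a chromosome end are retained with the
#' available bins and flagged.
#'
#' @param genes Gene tibble with `group` labels; only groups other than
#'   `"unassigned"` are profiled (restrict beforehand for finer control).
#' @param fraction_track A [repeat_fraction_track()].
#' @param n_bins Number of 1 kb bins (default 20).
#' @param bin_bp Bin width in bp (default 1000).
#' @param signed Use strand-oriented signed distance (default `FALSE`).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A `tss_profile` tibble: `group`, `bin`, `mean_pct`, `ci_lower`,
#'   `ci_upper`, `n_genes`; attribute `truncated_genes` lists genes with
#'   truncated windows.
#' @export
tss_repeat_profile <- function(genes, fraction_track, n_bins = 20,
                               bin_bp = 1000, signed = FALSE,
                               conf_level = 0.95) {
  check_track(fraction_track)
  g <- genes[genes$group != "unassigned", ]
  if (nrow(g) == 0) abort("No grouped genes to profile.")
  asm <- fraction_track$assembly
  step <- asm$step_bp
  D <- n_bins * bin_bp
  z <- qnorm(1 - (1 - conf_level) / 2)

  per_gene <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    ch <- g$chrom[i]; tss <- g$tss[i]
    n <- n_steps(asm, ch)
    j_lo <- max(1L, as.integer(floor((tss - D) / step)))
    j_hi <- min(n, as.integer(ceiling((tss + D) / step)) + 1L)
    j <- j_lo:j_hi
    mid <- (j - 1) * step + pmin(step, asm$seqlengths[[ch]] - (j - 1) * step) / 2
    dist <- mid - tss
    if (signed && g$strand[i] == "-") dist <- -dist
    if (signed) {
      b <- ifelse(dist >= 0, floor(dist / bin_bp) + 1,
                  -(floor(-dist / bin_bp) + 1))
      ok <- abs(b) <= n_bins
    } else {
      b <- floor(abs(dist) / bin_bp) + 1
      ok <- b <= n_bins
    }
    v <- fraction_track$values[[ch]][j]
    ok <- ok & !is.na(v)
    if (!any(ok)) return(NULL)
    means <- tapply(v[ok], b[ok], mean)
    tibble(gene_id = g$gene_id[i], group = g$group[i],
           bin = as.integer(names(means)), value = as.numeric(means),
           truncated = (tss - D < 0) || (tss + D > asm$seqlengths[[ch]]))
  })

  out <- per_gene |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(
      mean_pct = 100 * mean(.data$value),
      se = 100 * sd(.data$value) / sqrt(dplyr::n()),
      n_genes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lower = .data$mean_pct - z * .data$se,
                  ci_upper = .data$mean_pct + z * .data$se) |>
    dplyr::select("group", "bin", "mean_pct", "ci_lower", "ci_upper",
                  "n_genes") |>
    dplyr::arrange(.data$group, .data$bin)
  structure(out, class = c("tss_profile", class(out)),
            truncated_genes = sort(unique(per_gene$gene_id[per_gene$truncated])),
            bin_bp = bin_bp, signed = signed)
}

#' Group genes by wild-type MSL2 binding at a top-ratio cutoff
#'
#' An expressed gene is labelled `"bound"` iff any track step overlapping
#' its span is at or above the top-`top_percent` cutoff of the smoothed
#' MSL2 ratio track; other expressed genes are `"unbound"`.
#'
#' @param genes Gene tibble.
#' @param ratio_track Smoothed [genome_track()] of MSL2 log2 ratios.
#' @param top_percent Highest-ratio cutoff percentage (default 5).
#' @return The gene tibble with updated `group` labels.
#' @export
select_wildtype_bound_genes <- function(genes, ratio_track, top_percent = 5) {
  check_track(ratio_track)
  cutoff <- threshold_top_percent(ratio_track, top_percent)
  asm <- ratio_track$assembly
  step <- asm$step_bp
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    ch <- genes$chrom[i]
    if (!ch %in% track_chroms(ratio_track)) return(FALSE)
    n <- n_steps(asm, ch)
    j_lo <- max(1L, as.integer(floor(genes$start[i] / step)) + 1L)
    j_hi <- min(n, as.integer(ceiling(genes$end[i] / step)))
    if (j_lo > j_hi) return(FALSE)
    v <- ratio_track$values[[ch]][j_lo:j_hi]
    any(!is.na(v) & v >= cutoff)
  }, logical(1))
  genes$group <- dplyr::case_when(
    !genes$expressed ~ "unassigned",
    hit ~ "bound",
    TRUE ~ "unbound"
  )
  genes
}
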