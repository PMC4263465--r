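# Shared fixture builders and independent brute-force oracles.
# Oracles deliberately use naive loops and base R so they share no code
# with the implementation they check.

make_assembly <- function(len, step = 10, chrom = "chr") {
  genome_assembly(stats::setNames(len, chrom), step_bp = step)
}

make_track <- function(values, step = 10, chrom = "chr",
                       semantics = "log2_ratio") {
  asm <- make_assembly(length(values) * step, step = step, chrom = chrom)
  genome_track(stats::setNames(list(values), chrom), asm,
               semantics = semantics)
}

# random track with NA holes
random_track <- function(n, na_frac = 0.1, step = 10) {
  v <- rnorm(n)
  v[runif(n) < na_frac] <- NA
  make_track(v, step = step)
}

# --- brute-force median smoothing ---------------------------------------
# window for step i: steps [i - w/2, i + w/2 - 1]; lower median; NA when
# fewer than min_points non-NA values remain.
bf_median_smooth <- function(v, window_bp, min_points, step = 10) {
  w <- window_bp / step
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - w %/% 2)
    hi <- min(n, i + (w - w %/% 2) - 1)
    vals <- v[lo:hi]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= min_points) {
      s <- sort(vals)
      out[i] <- s[ceiling(length(s) / 2)]
    }
  }
  out
}

# --- brute-force region caller ------------------------------------------
# Enumerates unit chains and scans every 5-step window per region.
bf_call_regions <- function(v, step, cutoff, max_gap = 200,
                            min_length = 200, min_units = 5,
                            chrom_len = length(v) * step) {
  units <- which(!is.na(v) & v >= cutoff)
  if (length(units) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      score = numeric(0), peak_center = numeric(0),
                      n_units = integer(0)))
  }
  chains <- list(units[1])
  for (u in units[-1]) {
    last <- chains[[length(chains)]]
    prev <- last[length(last)]
    gap_bp <- (u - 1) * step - prev * step
    if (gap_bp <= max_gap) {
      chains[[length(chains)]] <- c(last, u)
    } else {
      chains[[length(chains) + 1]] <- u
    }
  }
  rows <- list()
  for (ch in chains) {
    first <- ch[1]; last <- ch[length(ch)]
    r_start <- (first - 1) * step
    r_end <- min(last * step, chrom_len)
    if (r_end - r_start < min_length) next
    if (length(ch) < min_units) next
    best <- -Inf; best_center <- NA_real_; found <- FALSE
    for (s in first:(last - 4)) {
      win <- v[s:(s + 4)]
      if (any(is.na(win))) next
      m <- mean(win)
      if (m > best) {
        best <- m
        best_center <- ((s - 1) * step + min((s + 4) * step, chrom_len)) / 2
        found <- TRUE
      }
    }
    if (!found) {
      ii <- (first:last)[!is.na(v[first:last])]
      for (j in seq_len(length(ii) - 4)) {
        m <- mean(v[ii[j:(j + 4)]])
        if (m > best) {
          best <- m
          best_center <- ((ii[j] - 1) * step +
                            min(ii[j + 4] * step, chrom_len)) / 2
        }
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      start = r_start, end = r_end, score = best,
      peak_center = best_center, n_units = length(ch))
  }
  if (length(rows) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      score = numeric(0), peak_center = numeric(0),
                      n_units = integer(0)))
  }
  do.call(rbind, rows)
}

# --- GenomicRanges nearest-gap oracle -----------------------------------
gr_gap_distance <- function(q, s) {
  qg <- GenomicRanges::GRanges(q$chrom,
                               IRanges::IRanges(q$start + 1, q$end))
  sg <- GenomicRanges::GRanges(s$chrom,
                               IRanges::IRanges(s$start + 1, s$end))
  hits <- GenomicRanges::distanceToNearest(qg, sg)
  d <- rep(NA_real_, length(qg))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

# write a small text file and return its path
tmp_file <- function(lines, ext = ".bed") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
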