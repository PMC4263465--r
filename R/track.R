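#' Construct a stepped genome signal track
#'
#' A `genome_track` holds one numeric value per assembly step and per
#' chromosome, with `NA` marking steps without data.  The object records the
#' step size, the smoothing state ("raw" or the smoothing window in bp) and
#' the value semantics (e.g. `"coverage"` or `"log2_ratio"`).
#'
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length `n_steps(assembly, chrom)`.
#' @param assembly A [genome_assembly()].
#' @param smoothing `"raw"` or the smoothing window size in bp.
#' @param semantics Free-text description of what the values mean.
#'
#' @return An object of class `genome_track`.
#' @export
genome_track <- function(values, assembly,
                         smoothing = "raw", semantics = "coverage") {
  check_assembly(assembly)
  if (!is.list(values) || is.null(names(values))) {
    abort("`values` must be a named list of numeric vectors.")
  }
  check_chrom(assembly, names(values))
  for (ch in names(values)) {
    v <- values[[ch]]
    if (!is.numeric(v)) abort(paste0("Values for ", ch, " are not numeric."))
    if (length(v) != n_steps(assembly, ch)) {
      abort(paste0("Values for ", ch, " have length ", length(v),
                   "; expected ", n_steps(assembly, ch), " steps."))
    }
    if (any(is.infinite(v))) {
      abort(paste0("Values for ", ch, " contain non-finite numbers; ",
                   "use NA for missing steps."))
    }
    values[[ch]] <- as.numeric(v)
  }
  structure(
    list(values = values, assembly = assembly,
         smoothing = smoothing, semantics = semantics),
    class = "genome_track"
  )
}

# all-missing track over the full assembly
empty_track <- function(assembly, semantics = "coverage") {
  vals <- lapply(names(assembly$seqlengths),
                 function(ch) rep(NA_real_, n_steps(assembly, ch)))
  names(vals) <- names(assembly$seqlengths)
  genome_track(vals, assembly, smoothing = "raw", semantics = semantics)
}

#' @export
print.genome_track <- function(x, ...) {
  nv <- sum(vapply(x$values, function(v) sum(!is.na(v)), 0))
  nt <- sum(vapply(x$values, length, 0))
  cat("<genome_track> ", x$semantics, ", smoothing: ",
      as.character(x$smoothing), "\n  ", length(x$values),
      " chromosome(s), ", nv, "/", nt, " steps with data\n", sep = "")
  invisible(x)
}

#' Extract the value vector of one chromosome
#'
#' @param track A [genome_track()].
#' @param chrom Chromosome name.
#' @return Numeric vector, one value per step (`NA` = missing).
#' @export
track_values <- function(track, chrom) {
  check_track(track)
  if (!chrom %in% names(track$values)) {
    abort(paste0("Track has no chromosome ", chrom, "."))
  }
  track$values[[chrom]]
}

#' Chromosomes covered by a track
#' @param track A [genome_track()].
#' @return Character vector of chromosome names.
#' @export
track_chroms <- function(track) {
  check_track(track)
  names(track$values)
}

#' Tidy a genome track into a step-level tibble
#'
#' @param x A [genome_track()].
#' @param drop_na Drop steps without data (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open step coordinates).
#' @export
tidy.genome_track <- function(x, drop_na = FALSE, ...) {
  out <- purrr::map_dfr(names(x$values), function(ch) {
    tibble(chrom = ch,
           start = step_starts(x$assembly, ch),
           end = step_ends(x$assembly, ch),
           value = x$values[[ch]])
  })
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

check_track <- function(track) {
  if (!inherits(track, "genome_track")) {
    abort("Expected a `genome_track` object.")
  }
  invisible(track)
}

check_same_assembly <- function(a, b) {
  if (!same_assembly(a$assembly, b$assembly)) {
    abort("Tracks are on different assemblies (chromosomes or step size differ).")
  }
  invisible(TRUE)
}
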