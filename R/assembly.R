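#' Define a genome assembly with a fixed step grid
#'
#' A genome assembly records the chromosome lengths of the analysed genome
#' together with the resolution (step size) at which all signal tracks are
#' represented.  Every track in the package carries one value per step; the
#' default 10 bp step matches the resolution at which enrichment ratios are
#' extracted genome-wide.
#'
#' @param seqlengths Named numeric vector of chromosome lengths in bp.
#'   Names are chromosome names and must be unique.
#' @param step_bp Step size in bp (default 10).  Track arrays hold one value
#'   per step; the last step of a chromosome may be partial.
#'
#' @return An object of class `genome_assembly`.
#' @examples
#' genome_assembly(c(chrX = 1e6, chr2L = 5e5))
#' @export
genome_assembly <- function(seqlengths, step_bp = 10) {
  if (is.null(names(seqlengths)) || any(names(seqlengths) == "") ||
      anyDuplicated(names(seqlengths))) {
    abort("`seqlengths` must be a named vector with unique, non-empty names.")
  }
  if (any(!is.finite(seqlengths)) || any(seqlengths <= 0)) {
    abort("All chromosome lengths must be positive and finite.")
  }
  if (!is.numeric(step_bp) || length(step_bp) != 1 || step_bp < 1) {
    abort("`step_bp` must be a single positive number.")
  }
  structure(
    list(seqlengths = seqlengths, step_bp = as.numeric(step_bp)),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$seqlengths), " chromosome(s), step ",
      x$step_bp, " bp\n", sep = "")
  for (ch in names(x$seqlengths)) {
    cat("  ", ch, ": ", format(x$seqlengths[[ch]], big.mark = ","), " bp (",
        n_steps(x, ch), " steps)\n", sep = "")
  }
  invisible(x)
}

#' Number of steps on a chromosome
#'
#' @param assembly A [genome_assembly()].
#' @param chrom Chromosome name.
#' @return Integer number of steps, `ceiling(length / step)`.
#' @export
n_steps <- function(assembly, chrom) {
  check_assembly(assembly)
  check_chrom(assembly, chrom)
  as.integer(ceiling(assembly$seqlengths[[chrom]] / assembly$step_bp))
}

# 0-based start coordinates of each step on `chrom`
step_starts <- function(assembly, chrom) {
  n <- n_steps(assembly, chrom)
  (seq_len(n) - 1) * assembly$step_bp
}

# 0-based (exclusive) end coordinates; the last step may be truncated
step_ends <- function(assembly, chrom) {
  pmin(step_starts(assembly, chrom) + assembly$step_bp,
       assembly$seqlengths[[chrom]])
}

# midpoint of each step's actual genomic span
step_midpoints <- function(assembly, chrom) {
  (step_starts(assembly, chrom) + step_ends(assembly, chrom)) / 2
}

check_assembly <- function(assembly) {
  if (!inherits(assembly, "genome_assembly")) {
    abort("Expected a `genome_assembly` object.")
  }
  invisible(assembly)
}

check_chrom <- function(assembly, chrom) {
  missing <- setdiff(chrom, names(assembly$seqlengths))
  if (length(missing) > 0) {
    abort(paste0("Unknown chromosome(s): ", paste(missing, collapse = ", ")))
  }
  invisible(chrom)
}

same_assembly <- function(a, b) {
  identical(a$step_bp, b$step_bp) &&
    identical(names(a$seqlengths), names(b$seqlengths)) &&
    isTRUE(all.equal(unname(a$seqlengths), unname(b$seqlengths)))
}
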