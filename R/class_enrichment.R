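#' Reads per kilobase per million mapped reads
#'
#' `count / ((length_bp / 1000) * (mapped_total / 1e6))`.  The denominator
#' uses the library's genome-mapped read total, not the repeat-mapped total.
#'
#' @param count Read count(s) for the feature (vectorized).
#' @param length_bp Feature length(s) in bp.
#' @param mapped_total Genome-mapped reads in the library.
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 2000, 1e7)  # 5
#' @export
rpkm <- function(count, length_bp, mapped_total) {
  if (any(length_bp <= 0)) abort("Feature length must be positive.")
  if (any(mapped_total <= 0)) abort("Mapped-read total must be positive.")
  if (any(count < 0)) abort("Counts must be non-negative.")
  count / ((length_bp / 1000) * (mapped_total / 1e6))
}

#' Per-repeat-class RPKM enrichment of ChIP over input
#'
#' Joins the ChIP and input count tables by class, computes each class's
#' RPKM in both libraries and their ratio, and attaches a bootstrap 95%
#' confidence interval obtained by resampling each library's repeat-mapped
#' reads over classes (multinomial resampling of the observed counts,
#' `B` replicates, seeded).  Classes with zero input RPKM get an undefined
#' (`NA`) ratio.
#'
#' @param chip,input Count tibbles (`class`, `length_bp`, `count`,
#'   `library_total`); the class universes must match.
#' @param B Bootstrap replicates (default 1000; 0 disables the CI).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A `class_enrichment` tibble: `class`, `length_bp`, `chip_rpkm`,
#'   `input_rpkm`, `ratio`, `ci_lower`, `ci_upper`, `chip_cov_per_nt`,
#'   `input_cov_per_nt` (mean per-nucleotide read count per million mapped
#'   reads).
#' @export
class_enrichment <- function(chip, input, B = 1000, seed = 1,
                             conf_level = 0.95) {
  only_chip <- setdiff(chip$class, input$class)
  only_input <- setdiff(input$class, chip$class)
  if (length(only_chip) > 0 || length(only_input) > 0) {
    abort(paste0("Class universes differ: ",
                 paste(c(only_chip, only_input), collapse = ", "),
                 " present in only one table."))
  }
  if (any(chip$length_bp[match(input$class, chip$class)] != input$length_bp)) {
    abort("Class lengths differ between the two tables.")
  }
  d <- dplyr::inner_join(
    dplyr::rename(chip, chip_count = "count", chip_total = "library_total"),
    dplyr::select(
      dplyr::rename(input, input_count = "count",
                    input_total = "library_total"),
      "class", "input_count", "input_total"),
    by = "class"
  )
  d$chip_rpkm <- rpkm(d$chip_count, d$length_bp, d$chip_total)
  d$input_rpkm <- rpkm(d$input_count, d$length_bp, d$input_total)
  d$ratio <- ifelse(d$input_rpkm > 0, d$chip_rpkm / d$input_rpkm, NA_real_)
  d$chip_cov_per_nt <- d$chip_count / d$length_bp / (d$chip_total / 1e6)
  d$input_cov_per_nt <- d$input_count / d$length_bp / (d$input_total / 1e6)

  if (B > 0) {
    alpha <- (1 - conf_level) / 2
    nc <- sum(d$chip_count); ni <- sum(d$input_count)
    if (nc == 0 || ni == 0) {
      d$ci_lower <- NA_real_; d$ci_upper <- NA_real_
    } else {
      reps <- withr::with_seed(seed, {
        cc <- rmultinom(B, nc, d$chip_count / nc)
        ci <- rmultinom(B, ni, d$input_count / ni)
        (cc / d$length_bp / d$chip_total) /
          ifelse(ci > 0, ci / d$length_bp / d$input_total, NA)
      })
      qs <- apply(reps, 1, quantile, probs = c(alpha, 1 - alpha),
                  na.rm = TRUE, names = FALSE)
      d$ci_lower <- qs[1, ]
      d$ci_upper <- qs[2, ]
    }
  } else {
    d$ci_lower <- NA_real_
    d$ci_upper <- NA_real_
  }
  out <- dplyr::select(d, "class", "length_bp", "chip_rpkm", "input_rpkm",
                       "ratio", "ci_lower", "ci_upper", "chip_cov_per_nt",
                       "input_cov_per_nt")
  structure(out, class = c("class_enrichment", class(out)),
            B = B, seed = seed, conf_level = conf_level)
}

#' Normalize per-nucleotide read depth to library size
#'
#' Divides each positional depth by the library's genome-mapped total in
#' millions.
#'
#' @param depth Numeric vector of per-position read counts.
#' @param mapped_total Genome-mapped reads in the library.
#' @return Normalized depths (reads per nucleotide per million mapped).
#' @export
per_nucleotide_coverage <- function(depth, mapped_total) {
  if (mapped_total <= 0) abort("Mapped-read total must be positive.")
  if (any(depth < 0)) abort("Depths must be non-negative.")
  depth / (mapped_total / 1e6)
}

#' Rank repeat classes by mutant-over-wild-type enrichment
#'
#' Orders classes by the mutant ChIP/input ratio relative to the wild-type
#' one (or by the mutant ratio alone when no wild-type table is given) and
#' flags classes above a fold-change report threshold.  Both axes (RPKM
#' and ratio) are carried through for scatter plotting.
#'
#' @param mutant A `class_enrichment` tibble for the mutant.
#' @param wildtype Optional `class_enrichment` tibble for the wild type.
#' @param fold_threshold Report threshold on the ranking statistic
#'   (default 2).
#' @return Tibble ordered by decreasing `relative_enrichment`, with a
#'   logical `flagged` column.
#' @export
rank_enriched_classes <- function(mutant, wildtype = NULL,
                                  fold_threshold = 2) {
  if (nrow(mutant) == 0) abort("Need at least one class.")
  out <- dplyr::rename(as_tibble(mutant),
                       mutant_chip_rpkm = "chip_rpkm",
                       mutant_input_rpkm = "input_rpkm",
                       mutant_ratio = "ratio")
  out <- dplyr::select(out, "class", "length_bp", "mutant_chip_rpkm",
                       "mutant_input_rpkm", "mutant_ratio")
  if (!is.null(wildtype)) {
    wt <- dplyr::select(
      dplyr::rename(as_tibble(wildtype),
                    wildtype_chip_rpkm = "chip_rpkm",
                    wildtype_input_rpkm = "input_rpkm",
                    wildtype_ratio = "ratio"),
      "class", "wildtype_chip_rpkm", "wildtype_input_rpkm",
      "wildtype_ratio")
    out <- dplyr::inner_join(out, wt, by = "class")
    out$relative_enrichment <- ifelse(
      !is.na(out$wildtype_ratio) & out$wildtype_ratio > 0,
      out$mutant_ratio / out$wildtype_ratio, NA_real_)
  } else {
    out$relative_enrichment <- out$mutant_ratio
  }
  out$flagged <- !is.na(out$relative_enrichment) &
    out$relative_enrichment >= fold_threshold
  dplyr::arrange(out, dplyr::desc(.data$relative_enrichment))
}
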