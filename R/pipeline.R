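#' End-to-end HAS association analysis
#'
#' Chains ratio-track construction, median smoothing, bound-region calling
#' and HAS nearest-distance binning with a seeded random control, writing
#' a regions BED, a distance-profile TSV and a summary JSON to the output
#' directory.  Deterministic given inputs and seed.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{chip_track, input_track}{bedGraph paths for ChIP and input
#'       coverage.}
#'     \item{has_bed}{BED path of high-affinity sites.}
#'     \item{chrom_sizes}{Two-column TSV (chrom, length) or a named
#'       numeric vector.}
#'     \item{out_dir}{Output directory.}
#'     \item{step_bp, pseudocount, window_bp, min_points}{Track parameters
#'       (defaults 10, 0.5, 500, preset).}
#'     \item{top_percent, max_gap, min_length, min_units, scope}{Calling
#'       parameters (defaults 1.5, 200, 200, 5, "genome").}
#'     \item{bin_width, n_bins, control_n, seed}{Distance parameters
#'       (defaults 5000, 8, 10000, 1).}
#'   }
#' @return Invisibly, a list with `regions`, `observed`, `control`,
#'   `cutoff` and the output paths.
#' @export
run_has_analysis <- function(config) {
  cfg <- pipeline_defaults(config)
  for (f in c("chip_track", "input_track", "has_bed")) {
    if (is.null(cfg[[f]])) abort(paste0("Config is missing `", f, "`."))
    if (!file.exists(cfg[[f]])) {
      abort(paste0("has-analysis: input file not found: ", cfg[[f]]))
    }
  }
  asm <- config_assembly(cfg)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
    message(sprintf("INFO [%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  chip <- stage("read-chip", read_coverage_track(cfg$chip_track, asm))
  input <- stage("read-input", read_coverage_track(cfg$input_track, asm))
  has <- stage("read-has", read_intervals(cfg$has_bed, asm))
  ratio <- stage("ratio",
                 compute_enrichment_ratio(chip, input, cfg$pseudocount))
  smooth <- stage("smooth",
                  median_smooth(ratio, cfg$window_bp, cfg$min_points))
  regions <- stage("callregions",
                   call_bound_regions(smooth, cfg$top_percent, cfg$max_gap,
                                      cfg$min_length, cfg$min_units,
                                      cfg$scope))
  has_chrom <- unique(has$chrom)[1]
  obs_regions <- regions[regions$chrom %in% unique(has$chrom), ]
  observed <- stage("hasdist", {
    d <- nearest_has_distance(obs_regions, has)
    bin_fractions(d, cfg$bin_width, cfg$n_bins, label = "observed")
  })
  control <- stage("control",
                   random_control(asm, has, has_chrom, n = cfg$control_n,
                                  seed = cfg$seed, bin_width = cfg$bin_width,
                                  n_bins = cfg$n_bins))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    regions = file.path(cfg$out_dir, "regions.bed"),
    profile = file.path(cfg$out_dir, "distance_profile.tsv"),
    summary = file.path(cfg$out_dir, "summary.json")
  )
  write_regions(regions, paths$regions)
  write_tsv_with_header(
    dplyr::bind_rows(as_tibble(observed), as_tibble(control)),
    paths$profile, cfg)
  jsonlite::write_json(list(
    tool = "mslchip", version = pkg_version(), seed = cfg$seed,
    n_regions = nrow(regions), cutoff = attr(regions, "cutoff"),
    params = cfg[c("pseudocount", "window_bp", "top_percent", "max_gap",
                   "min_length", "min_units", "scope", "bin_width",
                   "n_bins", "control_n")],
    observed_fractions = observed$fraction,
    control_fractions = control$fraction
  ), paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(list(regions = regions, observed = observed, control = control,
                 cutoff = attr(regions, "cutoff"), paths = paths))
}

#' End-to-end repeat analysis
#'
#' Computes the repeat-masked fraction track, the TSS repeat profile for
#' bound/unbound gene groups, and the per-repeat-class RPKM enrichment
#' table, writing both TSVs to the output directory.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{repeats_bed}{Repeat-masked intervals (BED).}
#'     \item{genes}{Gene annotation (GFF3/GTF/BED).}
#'     \item{chrom_sizes}{As in [run_has_analysis()].}
#'     \item{groups_tsv}{Optional TSV (`gene_id`, `group`, optionally
#'       `expressed`) assigning gene groups.}
#'     \item{regions_bed}{Optional called-regions BED used to label genes
#'       by overlap when no groups file is given.}
#'     \item{chip_classes, input_classes}{Optional count-table TSVs for
#'       the class enrichment stage.}
#'     \item{out_dir, window_bp, n_bins, bin_bp, flank, bootstrap_B, seed}{
#'       Parameters (defaults 200, 20, 1000, 0, 1000, 1).}
#'   }
#' @return Invisibly, a list with `tss_profile`, `class_enrichment` (or
#'   `NULL`) and output paths.
#' @export
run_repeat_analysis <- function(config) {
  cfg <- pipeline_defaults(config)
  for (f in c("repeats_bed", "genes")) {
    if (is.null(cfg[[f]])) abort(paste0("Config is missing `", f, "`."))
    if (!file.exists(cfg[[f]])) {
      abort(paste0("repeat-analysis: input file not found: ", cfg[[f]]))
    }
  }
  asm <- config_assembly(cfg)
  repeats <- read_intervals(cfg$repeats_bed, asm)
  genes <- read_gene_annotation(cfg$genes, asm)
  if (!is.null(cfg$groups_tsv)) {
    gtab <- readr::read_tsv(cfg$groups_tsv, comment = "#",
                            show_col_types = FALSE)
    genes$group <- gtab$group[match(genes$gene_id, gtab$gene_id)]
    genes$group[is.na(genes$group)] <- "unassigned"
    if ("expressed" %in% names(gtab)) {
      ex <- gtab$expressed[match(genes$gene_id, gtab$gene_id)]
      genes$expressed <- ifelse(is.na(ex), genes$expressed, ex)
    }
  } else if (!is.null(cfg$regions_bed)) {
    regions <- read_regions(cfg$regions_bed, asm)
    genes <- genes_overlapping_regions(genes, regions, flank = cfg$flank)
  }
  message("INFO [repeat-fraction] window ", cfg$window_bp, " bp")
  ftrack <- repeat_fraction_track(repeats, asm, cfg$window_bp)
  message("INFO [tss-profile] ", cfg$n_bins, " bins of ", cfg$bin_bp, " bp")
  profile <- tss_repeat_profile(genes, ftrack, cfg$n_bins, cfg$bin_bp)

  enr <- NULL
  if (!is.null(cfg$chip_classes) && !is.null(cfg$input_classes)) {
    message("INFO [class-enrichment] bootstrap B=", cfg$bootstrap_B)
    enr <- class_enrichment(read_class_counts(cfg$chip_classes),
                            read_class_counts(cfg$input_classes),
                            B = cfg$bootstrap_B, seed = cfg$seed)
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tss_profile = file.path(cfg$out_dir, "tss_profile.tsv"))
  write_tsv_with_header(as_tibble(profile), paths$tss_profile, cfg)
  if (!is.null(enr)) {
    paths$class_enrichment <- file.path(cfg$out_dir, "class_enrichment.tsv")
    write_tsv_with_header(as_tibble(enr), paths$class_enrichment, cfg)
  }
  invisible(list(tss_profile = profile, class_enrichment = enr,
                 paths = paths))
}

pipeline_defaults <- function(config) {
  defaults <- list(
    step_bp = 10, pseudocount = 0.5, window_bp = NULL, min_points = NULL,
    top_percent = 1.5, max_gap = 200, min_length = 200, min_units = 5,
    scope = "genome", bin_width = 5000, n_bins = 8, control_n = 10000,
    bin_bp = 1000, flank = 0, bootstrap_B = 1000, seed = 1L,
    out_dir = "mslchip_out"
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  # window and bin defaults differ between the two pipelines
  if (is.null(cfg$window_bp)) {
    cfg$window_bp <- if (!is.null(cfg$repeats_bed)) 200 else 500
  }
  if (is.null(config$n_bins) && !is.null(cfg$repeats_bed)) cfg$n_bins <- 20
  cfg
}

config_assembly <- function(cfg) {
  if (is.null(cfg$chrom_sizes)) abort("Config is missing `chrom_sizes`.")
  if (is.character(cfg$chrom_sizes) && length(cfg$chrom_sizes) == 1 &&
      file.exists(cfg$chrom_sizes)) {
    d <- readr::read_tsv(cfg$chrom_sizes, col_names = c("chrom", "length"),
                         show_col_types = FALSE)
    sl <- stats::setNames(d$length, d$chrom)
  } else {
    sl <- cfg$chrom_sizes
  }
  genome_assembly(sl, cfg$step_bp)
}

write_tsv_with_header <- function(x, path, cfg) {
  hdr <- sprintf("# mslchip %s | seed=%s", pkg_version(), cfg$seed)
  readr::write_lines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("mslchip"))
}
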