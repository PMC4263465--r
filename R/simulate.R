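#' Configuration for the synthetic-data generator
#'
#' The defaults describe the study conditions the downstream analyses are
#' validated under: a 1 Mb X-chromosome analog carrying 50 high-affinity
#' sites (HAS) of 500 bp at 4-fold ChIP enrichment with Gaussian log2-ratio
#' noise of sd 0.3, and a 17 Mb autosome analog carrying 400 expressed
#' genes (half labelled "bound", half "unbound") whose surroundings are
#' planted with repeat-masked intervals three times denser around bound
#' TSSs than around unbound ones.  Repeat-class read counts are Poisson
#' with planted ChIP/input folds of 5, 3 and 2 for the three classes the
#' analysis should recover (PROTOP_B, PROTOP_A, NTS_DM) and 1 elsewhere.
#'
#' @param chromosomes Named lengths of the simulated chromosomes.
#' @param step_bp Track step size.
#' @param has_chrom Chromosome carrying HAS.
#' @param n_has,has_width,has_fold Number, width (bp) and linear ChIP fold
#'   of the planted HAS.
#' @param noise_sd Gaussian sd of the background log2 ChIP/input ratio.
#' @param gradient_max_fold,gradient_decay_bp Pericentromeric enrichment
#'   gradient: linear fold at the centromere-proximal (right) chromosome
#'   end, decaying exponentially with the given length scale.  A max fold
#'   of 1 disables the gradient.
#' @param baseline_depth Mean coverage depth of the input track.
#' @param gene_chroms Chromosome(s) carrying genes.
#' @param n_genes,gene_length,gene_spacing,tss_jitter Gene count, span
#'   (bp), TSS spacing (bp) and uniform jitter (bp).
#' @param frac_bound Fraction of genes labelled "bound".
#' @param repeat_zone_bp Half-width of the planted repeat zone around each
#'   TSS.
#' @param cell_bp Repeat placement grid: one repeat per cell.
#' @param repeat_width_bound,repeat_width_unbound,repeat_width_background
#'   Repeat widths (bp) per 1 kb cell near bound TSSs, near unbound TSSs
#'   and elsewhere; the bound:unbound width ratio is the planted masked
#'   density ratio (default 240:80 = 3).
#' @param repeat_classes Tibble (`class`, `length_bp`, `fold`) of repeat
#'   consensus classes and planted ChIP/input folds.
#' @param repeat_reads_per_library Expected repeat-mapped reads in the
#'   input library, allocated across classes proportional to length.
#' @param chip_mapped_total,input_mapped_total Genome-mapped totals of the
#'   two libraries (RPKM denominators).
#' @param seed Master RNG seed; fixed seed gives byte-identical output.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    chromosomes = c(chrX = 1e6, chr2L = 17e6),
    step_bp = 10,
    has_chrom = "chrX", n_has = 50, has_width = 500, has_fold = 4,
    noise_sd = 0.3,
    gradient_max_fold = 1, gradient_decay_bp = 1e5,
    baseline_depth = 100,
    gene_chroms = "chr2L", n_genes = 400, gene_length = 2000,
    gene_spacing = 42000, tss_jitter = 1000,
    frac_bound = 0.5,
    repeat_zone_bp = 20000, cell_bp = 1000,
    repeat_width_bound = 240, repeat_width_unbound = 80,
    repeat_width_background = 80,
    repeat_classes = default_repeat_classes(),
    repeat_reads_per_library = 1e5,
    chip_mapped_total = 1e7, input_mapped_total = 1.2e7,
    seed = 1L) {
  cfg <- list(
    chromosomes = chromosomes, step_bp = step_bp,
    has_chrom = has_chrom, n_has = n_has, has_width = has_width,
    has_fold = has_fold, noise_sd = noise_sd,
    gradient_max_fold = gradient_max_fold,
    gradient_decay_bp = gradient_decay_bp,
    baseline_depth = baseline_depth,
    gene_chroms = gene_chroms, n_genes = n_genes,
    gene_length = gene_length, gene_spacing = gene_spacing,
    tss_jitter = tss_jitter, frac_bound = frac_bound,
    repeat_zone_bp = repeat_zone_bp, cell_bp = cell_bp,
    repeat_width_bound = repeat_width_bound,
    repeat_width_unbound = repeat_width_unbound,
    repeat_width_background = repeat_width_background,
    repeat_classes = repeat_classes,
    repeat_reads_per_library = repeat_reads_per_library,
    chip_mapped_total = chip_mapped_total,
    input_mapped_total = input_mapped_total,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$has_fold <= 0 || cfg$gradient_max_fold <= 0 ||
      any(cfg$repeat_classes$fold <= 0)) {
    abort("All enrichment folds must be positive.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (any(cfg$chromosomes <= 0) || cfg$n_has < 0 || cfg$n_genes < 0 ||
      cfg$has_width <= 0 || cfg$gene_length <= 0) {
    abort("Lengths and counts must be positive.")
  }
  if (nrow(cfg$repeat_classes) > 0 && any(cfg$repeat_classes$length_bp <= 0)) {
    abort("Repeat class consensus lengths must be positive.")
  }
  if (cfg$frac_bound < 0 || cfg$frac_bound > 1) {
    abort("`frac_bound` must be in [0, 1].")
  }
  invisible(cfg)
}

#' Default simulated repeat-class table
#'
#' Twelve Drosophila repeat-class analogs; PROTOP_B, PROTOP_A and NTS_DM
#' (the Hoppel transposon consensus halves and the rDNA non-transcribed
#' spacer) carry planted ChIP/input folds of 5, 3 and 2.
#'
#' @return Tibble with `class`, `length_bp`, `fold`.
#' @export
default_repeat_classes <- function() {
  tibble(
    class = c("PROTOP_B", "PROTOP_A", "NTS_DM", "ROO_I", "COPIA_DM",
              "F_DM", "DMRT1B", "GYPSY_DM", "JOCKEY_DM", "BLOOD_I",
              "DOC_DM", "HOBO_DM"),
    length_bp = c(1044, 1278, 4157, 9092, 5143, 4708, 4648, 7469,
                  5020, 7410, 4726, 2959),
    fold = c(5, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  )
}

#' Simulate a genome: assembly, HAS, genes, repeats and ground truth
#'
#' HAS are placed uniformly at random without overlap on `has_chrom`.
#' Genes are laid out on `gene_chroms` at regular spacing with jittered
#' TSSs and random strands; group labels ("bound"/"unbound") are assigned
#' at random in the configured proportion.  Repeat intervals are planted
#' on a fixed grid of `cell_bp` cells, one repeat per cell at a random
#' offset, with cell repeat width chosen by proximity to bound vs unbound
#' TSSs (within `repeat_zone_bp`), so the planted masked-density contrast
#' is exact by construction.
#'
#' @param config A [simulation_config()].
#' @return A list with `assembly`, `has` (IntervalSet tibble), `genes`
#'   (gene tibble with planted groups), `repeats` (IntervalSet tibble) and
#'   `ground_truth` (planted HAS, gene groups, class folds).
#' @export
simulate_genome <- function(config = simulation_config()) {
  validate_simulation_config(config)
  present <- intersect(config$gene_chroms, names(config$chromosomes))
  if (config$n_genes > 0 && length(present) == 0) {
    abort("None of `gene_chroms` is present in `chromosomes`.")
  }
  config$gene_chroms <- if (config$n_genes > 0) present else character(0)
  asm <- genome_assembly(config$chromosomes, config$step_bp)
  withr::with_seed(config$seed, {
    has <- place_has(config)
    genes <- place_genes(config)
    repeats <- place_repeats(config, genes)
  })
  list(
    assembly = asm,
    has = has,
    genes = genes,
    repeats = repeats,
    ground_truth = list(
      has = has,
      gene_groups = dplyr::select(genes, "gene_id", "group"),
      class_folds = config$repeat_classes
    )
  )
}

place_has <- function(config) {
  if (config$n_has == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  len <- config$chromosomes[[config$has_chrom]]
  free <- len - config$n_has * config$has_width
  if (free < 0) {
    abort(paste0(config$n_has, " HAS of ", config$has_width,
                 " bp do not fit on ", config$has_chrom, "."))
  }
  cuts <- sort(runif(config$n_has, 0, free))
  starts <- floor(cuts + (seq_len(config$n_has) - 1) * config$has_width)
  tibble(chrom = config$has_chrom, start = starts,
         end = starts + config$has_width,
         name = sprintf("HAS_%03d", seq_len(config$n_has)))
}

place_genes <- function(config) {
  if (config$n_genes == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), tss = numeric(),
                  strand = character(), expressed = logical(),
                  group = character()))
  }
  margin <- config$repeat_zone_bp + config$tss_jitter + config$gene_length
  slots <- purrr::map_dfr(config$gene_chroms, function(ch) {
    len <- config$chromosomes[[ch]]
    k <- floor((len - 2 * margin) / config$gene_spacing) + 1
    if (k < 1) return(NULL)
    tibble(chrom = ch,
           anchor = margin + (seq_len(k) - 1) * config$gene_spacing)
  })
  if (nrow(slots) < config$n_genes) {
    abort(paste0("Only ", nrow(slots), " gene slots fit on ",
                 paste(config$gene_chroms, collapse = ","),
                 " at spacing ", config$gene_spacing, "; requested ",
                 config$n_genes, "."))
  }
  slots <- slots[seq_len(config$n_genes), ]
  tss <- floor(slots$anchor +
                 runif(config$n_genes, -config$tss_jitter,
                       config$tss_jitter))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  n_bound <- round(config$n_genes * config$frac_bound)
  group <- sample(c(rep("bound", n_bound),
                    rep("unbound", config$n_genes - n_bound)))
  start <- ifelse(strand == "+", tss, tss - config$gene_length + 1)
  end <- ifelse(strand == "+", tss + config$gene_length, tss + 1)
  tibble(gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
         chrom = slots$chrom, start = start, end = end, tss = tss,
         strand = strand, expressed = TRUE, group = group)
}

place_repeats <- function(config, genes) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (length(config$gene_chroms) == 0) return(empty)
  dplyr::bind_rows(empty, purrr::map_dfr(config$gene_chroms, function(ch) {
    len <- config$chromosomes[[ch]]
    cell <- config$cell_bp
    n_cells <- floor(len / cell)
    if (n_cells < 1) return(NULL)
    centers <- (seq_len(n_cells) - 1) * cell + cell / 2
    g <- genes[genes$chrom == ch, ]
    width <- rep(config$repeat_width_background, n_cells)
    if (nrow(g) > 0) {
      for (grp in c("unbound", "bound")) {
        tss <- sort(g$tss[g$group == grp])
        if (length(tss) == 0) next
        d <- gap_distance(centers, centers, tss, tss + 1)
        wid <- if (grp == "bound") config$repeat_width_bound
               else config$repeat_width_unbound
        width[d <= config$repeat_zone_bp] <- wid
      }
    }
    off <- floor(runif(n_cells, 0, cell - width + 1))
    start <- (seq_len(n_cells) - 1) * cell + off
    tibble(chrom = ch, start = start, end = start + width)
  }))
}

#' Simulate ChIP and input coverage tracks
#'
#' The input track is a constant baseline depth with log-normal step noise;
#' the ChIP track multiplies the baseline by the HAS fold (a boxcar over
#' each planted site) and, when enabled, by a pericentromeric gradient
#' \eqn{1 + (f_{max}-1) e^{-(L - x)/\lambda}} rising towards the right
#' (centromere-proximal) chromosome end.  Noise is split evenly (in
#' variance) between the two tracks so the log2 ChIP/input ratio has the
#' configured `noise_sd` outside planted features.
#'
#' @param assembly A [genome_assembly()].
#' @param has HAS IntervalSet tibble (may be empty).
#' @param config A [simulation_config()].
#' @return List with `chip` and `input` coverage [genome_track()]s.
#' @export
simulate_ratio_tracks <- function(assembly, has, config = simulation_config()) {
  check_assembly(assembly)
  validate_simulation_config(config)
  withr::with_seed(config$seed + 1L, {
    chip_vals <- list(); input_vals <- list()
    for (ch in names(assembly$seqlengths)) {
      n <- n_steps(assembly, ch)
      len <- assembly$seqlengths[[ch]]
      mid <- step_midpoints(assembly, ch)
      s <- config$noise_sd / sqrt(2)
      a <- rnorm(n, 0, s)
      b <- rnorm(n, 0, s)
      fold <- rep(1, n)
      h <- has[has$chrom == ch, ]
      if (nrow(h) > 0) {
        for (i in seq_len(nrow(h))) {
          fold[mid >= h$start[i] & mid < h$end[i]] <- config$has_fold
        }
      }
      grad <- if (config$gradient_max_fold > 1) {
        1 + (config$gradient_max_fold - 1) *
          exp(-(len - mid) / config$gradient_decay_bp)
      } else rep(1, n)
      chip_vals[[ch]] <- config$baseline_depth * 2^a * fold * grad
      input_vals[[ch]] <- config$baseline_depth * 2^b
    }
  })
  list(
    chip = genome_track(chip_vals, assembly, semantics = "coverage"),
    input = genome_track(input_vals, assembly, semantics = "coverage")
  )
}

#' Simulate per-repeat-class read-count tables
#'
#' Input counts are Poisson with expectation proportional to class length
#' (summing to `repeat_reads_per_library`); ChIP counts multiply each
#' class's expectation by its planted fold and by the ratio of the two
#' library sizes, so the planted fold is exactly the expected RPKM ratio.
#'
#' @param config A [simulation_config()].
#' @return List with `chip` and `input` count tibbles (`class`,
#'   `length_bp`, `count`, `library_total`).
#' @export
simulate_repeat_class_counts <- function(config = simulation_config()) {
  validate_simulation_config(config)
  cls <- config$repeat_classes
  if (nrow(cls) == 0) abort("Repeat class list is empty.")
  p <- cls$length_bp / sum(cls$length_bp)
  lam_input <- config$repeat_reads_per_library * p
  lam_chip <- lam_input * cls$fold *
    (config$chip_mapped_total / config$input_mapped_total)
  withr::with_seed(config$seed + 2L, {
    chip_count <- rpois(nrow(cls), lam_chip)
    input_count <- rpois(nrow(cls), lam_input)
  })
  list(
    chip = tibble(class = cls$class, length_bp = cls$length_bp,
                  count = chip_count,
                  library_total = config$chip_mapped_total),
    input = tibble(class = cls$class, length_bp = cls$length_bp,
                   count = input_count,
                   library_total = config$input_mapped_total)
  )
}

#' Write a simulation to disk
#'
#' Emits chrom.sizes, HAS and repeat BED, gene GFF3, chip/input bedGraph,
#' count TSVs and a ground-truth JSON into `dir`.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param tracks Optional result of [simulate_ratio_tracks()].
#' @param counts Optional result of [simulate_repeat_class_counts()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, tracks = NULL, counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- tibble(chrom = names(sim$assembly$seqlengths),
                  length = as.integer(sim$assembly$seqlengths))
  readr::write_tsv(sizes, file.path(dir, "chrom.sizes"), col_names = FALSE)
  write_intervals(sim$has, file.path(dir, "has.bed"))
  write_intervals(sim$repeats, file.path(dir, "repeats.bed"))
  write_gene_annotation(sim$genes, file.path(dir, "genes.gff3"))
  gt <- list(
    has = sim$ground_truth$has,
    gene_groups = sim$ground_truth$gene_groups,
    class_folds = sim$ground_truth$class_folds
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  if (!is.null(tracks)) {
    write_bedgraph(tracks$chip, file.path(dir, "chip.bedgraph"))
    write_bedgraph(tracks$input, file.path(dir, "input.bedgraph"))
  }
  if (!is.null(counts)) {
    write_class_counts(counts$chip, file.path(dir, "chip_classes.tsv"))
    write_class_counts(counts$input, file.path(dir, "input_classes.tsv"))
  }
  invisible(dir)
}
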