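#' Read a coverage or signal track from bedGraph or wiggle
#'
#' Values are resampled onto the assembly's step grid: each step takes the
#' value of the source interval covering the step midpoint; steps whose
#' midpoint is not covered are missing.  For input that is already aligned to
#' the step grid (the normal case for stepped tracks) this is lossless.
#'
#' @param path A bedGraph (`.bedgraph`, `.bdg`, `.bg`) or wiggle (`.wig`)
#'   file, optionally gzip-compressed.
#' @param assembly A [genome_assembly()].
#' @param format `"auto"` (by extension), `"bedGraph"` or `"wig"`.
#' @param semantics Value semantics recorded on the returned track.
#'
#' @return A [genome_track()] spanning the whole assembly.
#' @export
read_coverage_track <- function(path, assembly, format = "auto",
                                semantics = "coverage") {
  check_assembly(assembly)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext,
      bedgraph = , bdg = , bg = "bedGraph",
      wig = "wig",
      abort(paste0("Cannot infer track format from extension '.", ext,
                   "'; pass `format` explicitly."))
    )
  }
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    return(empty_track(assembly, semantics = semantics))
  }
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0) return(empty_track(assembly, semantics = semantics))

  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
  check_chrom(assembly, unique(df$chrom))
  bad <- df$start < 0 | df$end > assembly$seqlengths[df$chrom]
  if (any(bad)) {
    abort(paste0("Track intervals outside chromosome bounds on ",
                 paste(unique(df$chrom[bad]), collapse = ", ")))
  }

  out <- empty_track(assembly, semantics = semantics)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort(paste0("Overlapping intervals on ", ch,
                   "; a track must define one value per position."))
    }
    mid <- step_midpoints(assembly, ch)
    idx <- findInterval(mid, d$start)
    hit <- idx >= 1 & mid < d$end[pmax(idx, 1)]
    v <- rep(NA_real_, length(mid))
    v[hit] <- d$value[idx[hit]]
    out$values[[ch]] <- v
  }
  out
}

#' Write a genome track as bedGraph
#'
#' Runs of equal values are merged into single intervals; missing steps are
#' omitted.
#'
#' @param track A [genome_track()].
#' @param path Output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  check_track(track)
  lines <- character(0)
  for (ch in track_chroms(track)) {
    v <- track$values[[ch]]
    if (all(is.na(v))) next
    starts <- step_starts(track$assembly, ch)
    ends <- step_ends(track$assembly, ch)
    key <- ifelse(is.na(v), "NA", format(v, digits = 15, trim = TRUE))
    r <- rle(key)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1
    keep <- r$values != "NA"
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch,
                              as.integer(starts[lo[keep]]),
                              as.integer(ends[hi[keep]]),
                              format(v[lo[keep]], digits = 15, trim = TRUE)))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3 to BED6 is accepted; coordinates stay 0-based half-open.  Records
#' are sorted by (chromosome, start) and validated against the assembly.
#'
#' @param path BED file, optionally gzip-compressed.
#' @param assembly A [genome_assembly()].
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name` and `score`, sorted by position.
#' @export
read_intervals <- function(path, assembly) {
  check_assembly(assembly)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(raw, "[ \t]+")
  ncol <- vapply(fields, length, 0L)
  if (any(ncol < 3)) {
    abort(paste0("BED line ", lineno[which(ncol < 3)[1]],
                 " has fewer than 3 fields."))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    abort(paste0("BED line ", lineno[bad], " has non-numeric coordinates."))
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(paste0("BED line ", lineno[bad[1]], ": start >= end (",
                 out$start[bad[1]], " >= ", out$end[bad[1]], ")."))
  }
  if (max(ncol) >= 4) out$name <- vapply(fields, function(f) {
    if (length(f) >= 4) f[[4]] else NA_character_
  }, "")
  if (max(ncol) >= 5) out$score <- as.numeric(vapply(fields, function(f) {
    if (length(f) >= 5) f[[5]] else NA_character_
  }, ""))
  if (max(ncol) >= 6) out$strand <- vapply(fields, function(f) {
    if (length(f) >= 6) f[[6]] else NA_character_
  }, "")
  check_chrom(assembly, unique(out$chrom))
  oob <- out$end > assembly$seqlengths[out$chrom]
  if (any(oob)) {
    abort(paste0("BED line ", lineno[which(oob)[1]],
                 " extends past the end of ", out$chrom[which(oob)[1]], "."))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(x)))
  extra <- intersect(c("name", "score", "strand"), names(x))
  # BED columns are positional: fill gaps with defaults
  d <- tibble(chrom = x$chrom, start = as.integer(x$start),
              end = as.integer(x$end))
  if (length(extra) > 0) {
    d$name <- if ("name" %in% extra) x$name else "."
    if (any(c("score", "strand") %in% extra)) {
      d$score <- if ("score" %in% extra) x$score else 0
      if ("strand" %in% extra) d$strand <- x$strand
    }
  }
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation from GFF3/GTF or BED
#'
#' The transcription start site (TSS) is the 0-based position of the first
#' transcribed base: the interval start for `+` genes and `end - 1` for `-`
#' genes (GFF coordinates are converted from 1-based closed on read).
#'
#' @param path GFF3 (`.gff`, `.gff3`), GTF (`.gtf`) or BED6 file; gzip ok.
#' @param assembly A [genome_assembly()].
#' @param expressed_ids Optional character vector of gene ids to flag as
#'   expressed.  `NULL` (default) marks every gene expressed unless the
#'   GFF record carries an `expressed` attribute.
#' @param feature_type GFF/GTF feature type to keep (default `"gene"`; set
#'   `NULL` to keep all records).
#'
#' @return A tibble of genes: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `tss`, `strand`, `expressed`, `group` (initially
#'   `"unassigned"`).
#' @export
read_gene_annotation <- function(path, assembly, expressed_ids = NULL,
                                 feature_type = "gene") {
  check_assembly(assembly)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  base <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("bed")) {
    b <- read_intervals(path, assembly)
    if (!all(c("name", "strand") %in% names(b))) {
      abort("BED gene input needs name (col 4) and strand (col 6).")
    }
    genes <- tibble(gene_id = b$name, chrom = b$chrom,
                    start = b$start, end = b$end, strand = b$strand)
    expressed_attr <- rep(NA, nrow(genes))
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(path, format = if (ext == "gtf") "gtf" else "gff3")
    if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == feature_type]
    }
    if (length(gr) == 0) abort("No gene records found.")
    m <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(m)) as.character(m$ID)
          else if ("gene_id" %in% names(m)) as.character(m$gene_id)
          else if ("Name" %in% names(m)) as.character(m$Name)
          else abort("Gene records lack an ID/gene_id attribute.")
    genes <- tibble(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr))
    )
    expressed_attr <- if ("expressed" %in% names(m)) {
      as.logical(m$expressed)
    } else rep(NA, nrow(genes))
  } else {
    abort(paste0("Unsupported gene annotation extension '.", ext, "'."))
  }

  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1]
    abort(paste0("Gene ", bad, " has no usable strand (+/- required)."))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("Duplicate gene id: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  check_chrom(assembly, unique(genes$chrom))
  oob <- genes$start < 0 | genes$end > assembly$seqlengths[genes$chrom]
  if (any(oob)) {
    abort(paste0("Gene ", genes$gene_id[which(oob)[1]],
                 " lies outside its chromosome."))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$expressed <- if (!is.null(expressed_ids)) {
    genes$gene_id %in% expressed_ids
  } else {
    ifelse(is.na(expressed_attr), TRUE, expressed_attr)
  }
  genes$group <- "unassigned"
  dplyr::arrange(
    dplyr::select(genes, "gene_id", "chrom", "start", "end", "tss",
                  "strand", "expressed", "group"),
    .data$chrom, .data$start
  )
}

#' Write a gene annotation as GFF3
#'
#' @param genes Gene tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  attrs <- sprintf("ID=%s;expressed=%s;group=%s", genes$gene_id,
                   ifelse(genes$expressed, "TRUE", "FALSE"), genes$group)
  lines <- sprintf("%s\tmslchip\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, as.integer(genes$start + 1),
                   as.integer(genes$end), genes$strand, attrs)
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write called bound regions as BED6+2
#'
#' Columns are chrom, start, end, name, a BED-compliant integer score
#' (region score x 1000, truncated into [0, 1000]), strand ".", the true
#' region score (column 7) and the peak centre (column 8).  The file
#' round-trips through [read_regions()].
#'
#' @param regions A bound-region tibble from [call_bound_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  bed_score <- pmax(0L, pmin(1000L, as.integer(trunc(regions$score * 1000))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s",
                   regions$chrom, as.integer(regions$start),
                   as.integer(regions$end), regions$name, bed_score,
                   format(regions$score, digits = 15, trim = TRUE),
                   format(regions$peak_center, digits = 15, trim = TRUE))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read bound regions written by [write_regions()]
#'
#' @param path BED6+2 file.
#' @param assembly A [genome_assembly()].
#' @return A bound-region tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `peak_center`).
#' @export
read_regions <- function(path, assembly) {
  check_assembly(assembly)
  raw <- readr::read_lines(path)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^(#|track|browser)", raw)]
  if (length(raw) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(),
                  peak_center = numeric()))
  }
  f <- strsplit(raw, "\t")
  if (any(vapply(f, length, 0L) < 8)) {
    abort("Region BED must have 8 columns (BED6 + score + peak centre).")
  }
  out <- tibble(
    chrom = vapply(f, `[[`, "", 1),
    start = as.numeric(vapply(f, `[[`, "", 2)),
    end = as.numeric(vapply(f, `[[`, "", 3)),
    name = vapply(f, `[[`, "", 4),
    score = as.numeric(vapply(f, `[[`, "", 7)),
    peak_center = as.numeric(vapply(f, `[[`, "", 8))
  )
  check_chrom(assembly, unique(out$chrom))
  if (any(out$start >= out$end)) abort("Region with start >= end.")
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Read / write per-repeat-class read count tables
#'
#' Tab-separated with columns `class`, `length_bp`, `count`,
#' `library_total` (genome-mapped reads of the library).  Lines starting
#' with `#` are ignored.
#'
#' @param path TSV file.
#' @return A tibble with the four columns above.
#' @export
read_class_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("class", "length_bp", "count", "library_total")
  if (!all(need %in% names(d))) {
    abort(paste0("Count table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  as_tibble(d[need])
}

#' @rdname read_class_counts
#' @param counts Count tibble to write.
#' @export
write_class_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Convert RepeatMasker .out annotation to BED
#'
#' Utility converter; the analysis path itself consumes BED.  RepeatMasker
#' `.out` positions are 1-based closed and become 0-based half-open.
#'
#' @param path RepeatMasker `.out` file.
#' @param bed_path Output BED path.
#' @return `bed_path`, invisibly.
#' @export
repeatmasker_to_bed <- function(path, bed_path) {
  raw <- readr::read_lines(path)
  raw <- raw[-seq_len(min(3, length(raw)))]           # banner lines
  raw <- raw[nzchar(trimws(raw))]
  f <- strsplit(trimws(raw), "[ \t]+")
  keep <- vapply(f, length, 0L) >= 11
  f <- f[keep]
  lines <- vapply(f, function(x) {
    sprintf("%s\t%d\t%d\t%s", x[[5]], as.integer(x[[6]]) - 1L,
            as.integer(x[[7]]), x[[10]])
  }, "")
  readr::write_lines(lines, bed_path)
  invisible(bed_path)
}
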