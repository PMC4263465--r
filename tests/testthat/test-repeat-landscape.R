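test_that("repeat fraction track matches direct window counting", {
  asm <- genome_assembly(c(chr = 1000), step_bp = 10)
  none <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric())
  expect_equal(track_values(repeat_fraction_track(none, asm), "chr"),
               rep(0, 100))

  full <- tibble::tibble(chrom = "chr", start = 0, end = 1000)
  expect_equal(track_values(repeat_fraction_track(full, asm), "chr"),
               rep(1, 100))

  # single 50 bp repeat fully inside a 200 bp window -> 0.25 there
  one <- tibble::tibble(chrom = "chr", start = 400, end = 450)
  v <- track_values(repeat_fraction_track(one, asm), "chr")
  expect_equal(max(v), 0.25)
  expect_equal(v[45], 0.25)

  # brute-force oracle over all steps, random repeats, with truncation
  withr::with_seed(13, {
    reps <- tibble::tibble(chrom = "chr",
                           start = sort(sample(0:950, 12)))
    reps$end <- pmin(1000, reps$start + sample(20:120, 12, replace = TRUE))
    got <- track_values(repeat_fraction_track(reps, asm), "chr")
    # merge overlaps for the oracle
    m <- IRanges::reduce(IRanges::IRanges(reps$start + 1, reps$end))
    want <- vapply(1:100, function(i) {
      lo <- max(0, (i - 1 - 10) * 10)
      hi <- min(1000, (i + 9) * 10)
      ov <- sum(pmax(0, pmin(IRanges::end(m), hi) -
                       pmax(IRanges::start(m) - 1, lo)))
      ov / (hi - lo)
    }, 0)
    expect_equal(got, want)
    expect_true(all(got >= 0 & got <= 1))
  })
})

test_that("total masked bp is conserved up to edge effects", {
  withr::with_seed(4, {
    asm <- genome_assembly(c(chr = 50000), step_bp = 10)
    reps <- tibble::tibble(chrom = "chr",
                           start = sort(sample(0:49000, 40)))
    reps$end <- pmin(50000, reps$start + sample(50:400, 40, replace = TRUE))
    m <- IRanges::reduce(IRanges::IRanges(reps$start + 1, reps$end))
    total <- sum(IRanges::width(m))
    tr <- repeat_fraction_track(reps, asm, window_bp = 200)
    recon <- sum(track_values(tr, "chr")) * 10
    expect_lt(abs(recon - total), 2 * 200)
  })
})

test_that("TSS profile recovers known masking levels per group", {
  asm <- genome_assembly(c(chr = 60000), step_bp = 10)
  # constant fraction track: every bin should report 30%
  tr <- genome_track(list(chr = rep(0.3, 6000)), asm,
                     semantics = "repeat_fraction")
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr", start = c(25000, 32000),
    end = c(27000, 34000), tss = c(25000, 32000), strand = "+",
    expressed = TRUE, group = "bound")
  prof <- tss_repeat_profile(genes, tr, n_bins = 20, bin_bp = 1000)
  expect_equal(nrow(prof), 20)
  expect_equal(prof$mean_pct, rep(30, 20))
  expect_equal(prof$n_genes, rep(2L, 20))

  # two genes sitting on 10% and 30% plateaus average to 20%
  v <- rep(0.1, 6000); v[3001:6000] <- 0.3
  tr2 <- genome_track(list(chr = v), asm, semantics = "repeat_fraction")
  genes2 <- genes
  genes2$tss <- c(10000, 50000)   # deep inside each plateau
  genes2$start <- genes2$tss; genes2$end <- genes2$tss + 2000
  prof2 <- tss_repeat_profile(genes2, tr2, n_bins = 5, bin_bp = 1000)
  expect_equal(prof2$mean_pct, rep(20, 5))

  # CI narrows with gene count; replicating the two genes 4x scales the
  # standard error by exactly 1/sqrt(n-1) here (sample sd of duplicated
  # values), i.e. hw/sqrt(7)
  genes4 <- dplyr::bind_rows(genes2,
                             dplyr::mutate(genes2, gene_id = c("g3", "g4")),
                             dplyr::mutate(genes2, gene_id = c("g5", "g6")),
                             dplyr::mutate(genes2, gene_id = c("g7", "g8")))
  prof4 <- tss_repeat_profile(genes4, tr2, n_bins = 5, bin_bp = 1000)
  hw2 <- (prof2$ci_upper - prof2$ci_lower)[1]
  hw4 <- (prof4$ci_upper - prof4$ci_lower)[1]
  expect_equal(hw4, hw2 / sqrt(7))
})

test_that("profile is invariant to gene order and flags truncation", {
  withr::with_seed(8, {
    asm <- genome_assembly(c(chr = 100000), step_bp = 10)
    tr <- genome_track(list(chr = runif(10000)), asm,
                       semantics = "repeat_fraction")
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:6), chrom = "chr",
      tss = c(500, 30000, 45000, 60000, 75000, 99000),
      strand = rep(c("+", "-"), 3), expressed = TRUE,
      group = rep(c("bound", "unbound"), each = 3))
    genes$start <- genes$tss; genes$end <- pmin(genes$tss + 2000, 1e5)
    p1 <- tss_repeat_profile(genes, tr)
    p2 <- tss_repeat_profile(genes[sample(1:6), ], tr)
    expect_equal(as.data.frame(p1), as.data.frame(p2))
    # genes near the ends have truncated windows but are retained
    expect_setequal(attr(p1, "truncated_genes"), c("g1", "g6"))
    expect_true(all(p1$mean_pct >= 0 & p1$mean_pct <= 100))
  })
})

test_that("signed profiling orients bins by strand", {
  asm <- genome_assembly(c(chr = 40000), step_bp = 10)
  v <- rep(0, 4000); v[2001:4000] <- 1   # masked only downstream of 20 kb
  tr <- genome_track(list(chr = v), asm, semantics = "repeat_fraction")
  gplus <- tibble::tibble(gene_id = "gp", chrom = "chr", start = 20000,
                          end = 22000, tss = 20000, strand = "+",
                          expressed = TRUE, group = "bound")
  gminus <- dplyr::mutate(gplus, gene_id = "gm", strand = "-",
                          start = 18000, end = 20001, tss = 20000)
  pp <- tss_repeat_profile(gplus, tr, n_bins = 5, signed = TRUE)
  pm <- tss_repeat_profile(gminus, tr, n_bins = 5, signed = TRUE)
  expect_equal(pp$mean_pct[pp$bin > 0], rep(100, 5), tolerance = 0.06)
  expect_equal(pm$mean_pct[pm$bin > 0], rep(0, 5), tolerance = 0.06)
})

test_that("wild-type bound genes are selected by top-ratio cutoff", {
  withr::with_seed(30, {
    asm <- genome_assembly(c(chr = 50000), step_bp = 10)
    v <- rnorm(5000)
    tr <- genome_track(list(chr = v), asm, semantics = "log2_ratio")
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:50), chrom = "chr",
      start = (0:49) * 1000, end = (0:49) * 1000 + 800,
      tss = (0:49) * 1000, strand = "+", expressed = TRUE,
      group = "unassigned")
    sel <- select_wildtype_bound_genes(genes, tr, top_percent = 5)
    # direct counting oracle: gene bound iff its span holds a top-5% step
    cut <- sort(v, decreasing = TRUE)[ceiling(0.05 * 5000)]
    want <- vapply(seq_len(50), function(i) {
      steps <- (genes$start[i] / 10 + 1):(genes$end[i] / 10)
      any(v[steps] >= cut)
    }, logical(1))
    expect_equal(sel$group == "bound", want)

    # constant track: everything ties at the cutoff -> all bound
    ct <- genome_track(list(chr = rep(1, 5000)), asm,
                       semantics = "log2_ratio")
    expect_true(all(
      select_wildtype_bound_genes(genes, ct)$group == "bound"))

    # only the gene covering the single maximum survives a tiny cutoff
    v2 <- rnorm(5000); v2[155] <- 100  # inside gene 2's span
    t2 <- genome_track(list(chr = v2), asm, semantics = "log2_ratio")
    sel2 <- select_wildtype_bound_genes(genes, t2, top_percent = 0.01)
    expect_equal(sel2$group == "bound",
                 seq_len(50) == 2)
  })
})
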