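test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(chromosomes = c(chrX = 2e5, chr2L = 5e5),
                           n_has = 8, n_genes = 10, gene_spacing = 45000,
                           seed = 99)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  for (d in c(d1, d2)) {
    sim <- simulate_genome(cfg)
    tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
    counts <- simulate_repeat_class_counts(cfg)
    write_simulation(sim, d, tracks, counts)
  }
  files <- list.files(d1)
  expect_true(length(files) >= 7)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed, different data
  sim2 <- simulate_genome(simulation_config(
    chromosomes = c(chrX = 2e5, chr2L = 5e5), n_has = 8, n_genes = 10,
    gene_spacing = 45000, seed = 100))
  expect_false(identical(simulate_genome(cfg)$has, sim2$has))
})

test_that("planted HAS are disjoint, in bounds, and must fit", {
  cfg <- simulation_config(chromosomes = c(chrX = 1e6), n_has = 50,
                           has_width = 500, n_genes = 0, seed = 1)
  sim <- simulate_genome(cfg)
  h <- sim$has
  expect_equal(nrow(h), 50)
  expect_true(all(h$start >= 0 & h$end <= 1e6))
  expect_true(all(h$start[-1] >= h$end[-50]))      # sorted, non-overlapping
  expect_error(
    simulate_genome(simulation_config(chromosomes = c(chrX = 1e4),
                                      n_has = 50, has_width = 500,
                                      n_genes = 0)),
    "fit")
})

test_that("planted repeat density contrasts bound vs unbound genes", {
  sim <- simulate_genome(simulation_config(seed = 12))
  genes <- sim$genes
  expect_equal(sum(genes$group == "bound"), 200)
  masked_near <- function(g) {
    vapply(seq_len(nrow(g)), function(i) {
      lo <- g$tss[i] - 10000; hi <- g$tss[i] + 10000
      r <- sim$repeats[sim$repeats$chrom == g$chrom[i], ]
      sum(pmax(0, pmin(r$end, hi) - pmax(r$start, lo)))
    }, 0)
  }
  mb <- mean(masked_near(genes[genes$group == "bound", ]))
  mu <- mean(masked_near(genes[genes$group == "unbound", ]))
  expect_gt(mb / mu, 2.5)
  expect_lt(mb / mu, 3.5)
})

test_that("noiseless tracks reproduce the planted fold exactly", {
  cfg <- simulation_config(chromosomes = c(chrX = 1e5), n_has = 5,
                           has_width = 500, has_fold = 4, noise_sd = 0,
                           n_genes = 0, seed = 3)
  sim <- simulate_genome(cfg)
  tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
  r <- compute_enrichment_ratio(tracks$chip, tracks$input,
                                pseudocount = 1e-12, normalize = FALSE)
  v <- track_values(r, "chrX")
  mids <- (seq_along(v) - 1) * 10 + 5
  inside <- vapply(mids, function(m) {
    any(m >= sim$has$start & m < sim$has$end)
  }, logical(1))
  expect_equal(v[inside], rep(2, sum(inside)), tolerance = 1e-9)
  expect_equal(v[!inside], rep(0, sum(!inside)), tolerance = 1e-9)
})

test_that("the pericentromeric gradient decays exponentially", {
  cfg <- simulation_config(chromosomes = c(chrX = 4e5), n_has = 0,
                           n_genes = 0, noise_sd = 0,
                           gradient_max_fold = 2, gradient_decay_bp = 1e5,
                           seed = 4)
  sim <- simulate_genome(cfg)
  tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
  r <- track_values(compute_enrichment_ratio(tracks$chip, tracks$input,
                                             pseudocount = 1e-12,
                                             normalize = FALSE), "chrX")
  n <- length(r)
  # log2 ratio approaches 1 at the centromere-proximal (right) end
  expect_equal(r[n], 1, tolerance = 1e-3)
  # and matches the stated decay at an interior point
  mid <- (n / 2 - 1) * 10 + 5
  expect_equal(r[n / 2], log2(1 + exp(-(4e5 - mid) / 1e5)),
               tolerance = 1e-9)
  expect_true(all(diff(r) >= 0))
})

test_that("a fold-1 simulation yields statistically matched tracks", {
  cfg <- simulation_config(chromosomes = c(chrX = 1e5), n_has = 0,
                           n_genes = 0, noise_sd = 0.3, seed = 14)
  sim <- simulate_genome(cfg)
  tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
  ks <- stats::ks.test(track_values(tracks$chip, "chrX"),
                       track_values(tracks$input, "chrX"))
  expect_gt(ks$p.value, 0.01)
})

test_that("count simulation validates classes and matches null folds", {
  expect_error(simulate_repeat_class_counts(simulation_config(
    repeat_classes = tibble::tibble(class = "X", length_bp = 0,
                                    fold = 1))),
    "length")
  cfg <- simulation_config(
    repeat_classes = dplyr::mutate(default_repeat_classes(), fold = 1),
    seed = 15)
  counts <- simulate_repeat_class_counts(cfg)
  e <- class_enrichment(counts$chip, counts$input, B = 0)
  expect_lt(abs(mean(e$ratio) - 1), 0.1)
  # library totals are carried through
  expect_equal(unique(counts$chip$library_total), 1e7)
  expect_equal(unique(counts$input$library_total), 1.2e7)
})

test_that("planted sites are recovered end to end on a small genome", {
  cfg <- simulation_config(chromosomes = c(chrX = 3e5), n_has = 15,
                           n_genes = 0, seed = 16)
  sim <- simulate_genome(cfg)
  tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
  sm <- median_smooth(compute_enrichment_ratio(tracks$chip, tracks$input),
                      500)
  regions <- call_bound_regions(sm)
  expect_gt(nrow(regions), 0)
  d <- nearest_has_distance(regions, sim$has)$has_distance
  expect_gte(mean(d <= 1000), 0.9)
  hit_has <- vapply(seq_len(nrow(sim$has)), function(i) {
    any(regions$start < sim$has$end[i] + 1000 &
          regions$end > sim$has$start[i] - 1000)
  }, logical(1))
  expect_gte(mean(hit_has), 0.9)
})

test_that("a null simulation calls few regions and no HAS association", {
  cfg <- simulation_config(chromosomes = c(chrX = 1e6), n_has = 50,
                           has_fold = 1, n_genes = 0, seed = 17)
  sim <- simulate_genome(cfg)
  tracks <- simulate_ratio_tracks(sim$assembly, sim$has, cfg)
  sm <- median_smooth(compute_enrichment_ratio(tracks$chip, tracks$input),
                      500)
  regions <- call_bound_regions(sm)
  # steps inside surviving regions stay near the nominal 1.5% of units
  frac_in_regions <- sum(regions$end - regions$start) / 1e6
  expect_lte(frac_in_regions, 0.03)
  if (nrow(regions) >= 5) {
    obs <- nearest_has_distance(regions, sim$has)$has_distance
    ctl <- random_control(sim$assembly, sim$has, "chrX", n = 10000,
                          seed = 18)
    # observed first-bin count consistent with the random expectation
    bt <- stats::binom.test(sum(obs < 5000), length(obs),
                            p = ctl$fraction[1])
    expect_gt(bt$p.value, 0.01)
  }
})
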