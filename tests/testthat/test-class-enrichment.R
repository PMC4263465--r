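test_that("RPKM follows its closed form and scale invariances", {
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  # doubling both count and total leaves RPKM unchanged
  expect_equal(rpkm(200, 2000, 2e7), rpkm(100, 2000, 1e7))
  # linear in counts, inverse-linear in length
  expect_equal(rpkm(300, 2000, 1e7), 3 * rpkm(100, 2000, 1e7))
  expect_equal(rpkm(100, 4000, 1e7), rpkm(100, 2000, 1e7) / 2)
  expect_error(rpkm(10, 0, 1e7), "length")
  expect_error(rpkm(10, 100, 0), "total")
})

test_that("class enrichment ratios come from RPKM pairs", {
  chip <- tibble::tibble(class = c("A", "B"), length_bp = c(1000, 2000),
                         count = c(100, 50), library_total = 1e7)
  input <- tibble::tibble(class = c("A", "B"), length_bp = c(1000, 2000),
                          count = c(20, 50), library_total = 1e7)
  e <- class_enrichment(chip, input, B = 0)
  expect_equal(e$chip_rpkm[e$class == "A"], 10)
  expect_equal(e$input_rpkm[e$class == "A"], 2)
  expect_equal(e$ratio, c(5, 1))
  # per-nucleotide coverage column is RPKM / 1000
  expect_equal(e$chip_cov_per_nt, e$chip_rpkm / 1000)

  # identical tables -> all ratios exactly 1
  eid <- class_enrichment(chip, chip, B = 0)
  expect_equal(eid$ratio, c(1, 1))

  # zero input -> undefined ratio, no error
  input0 <- dplyr::mutate(input, count = c(0, 50))
  e0 <- class_enrichment(chip, input0, B = 0)
  expect_true(is.na(e0$ratio[e0$class == "A"]))

  # mismatched universes fail, naming the class
  expect_error(class_enrichment(chip, input[1, ]), "B")
})

test_that("per-nucleotide coverage normalizes to millions mapped", {
  expect_equal(per_nucleotide_coverage(7, 1e7), 0.7)
  expect_equal(per_nucleotide_coverage(rep(0, 5), 1e7), rep(0, 5))
  expect_equal(per_nucleotide_coverage(4, 2e7),
               per_nucleotide_coverage(8, 4e7) * 1)
  expect_equal(per_nucleotide_coverage(4, 2e7),
               per_nucleotide_coverage(4, 1e7) / 2)
})

test_that("planted folds are estimated within Poisson error", {
  cfg <- simulation_config(seed = 77)
  counts <- simulate_repeat_class_counts(cfg)
  e <- class_enrichment(counts$chip, counts$input, B = 500, seed = 78)
  est <- e$ratio[match(c("PROTOP_B", "PROTOP_A", "NTS_DM"), e$class)]
  expect_true(all(est >= c(4, 2.4, 1.6) & est <= c(6, 3.6, 2.4)))
  null_est <- e$ratio[!e$class %in% c("PROTOP_B", "PROTOP_A", "NTS_DM")]
  expect_true(all(abs(null_est - 1) < 0.25))
})

test_that("bootstrap CIs cover the planted fold at near-nominal rate", {
  covered <- vapply(1:60, function(s) {
    cfg <- simulation_config(
      seed = 1000 + s,
      repeat_classes = tibble::tibble(
        class = c("HOT", sprintf("null%d", 1:5)),
        length_bp = c(2000, 1500, 3000, 2500, 1800, 4000),
        fold = c(5, 1, 1, 1, 1, 1)))
    counts <- simulate_repeat_class_counts(cfg)
    e <- class_enrichment(counts$chip, counts$input, B = 400,
                          seed = 2000 + s)
    i <- which(e$class == "HOT")
    e$ci_lower[i] <= 5 && 5 <= e$ci_upper[i]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("ranking recovers planted folds in order and nulls stay quiet", {
  cfg <- simulation_config(seed = 5)
  counts <- simulate_repeat_class_counts(cfg)
  e <- class_enrichment(counts$chip, counts$input, B = 0)
  rk <- rank_enriched_classes(e)
  expect_equal(rk$class[1:3], c("PROTOP_B", "PROTOP_A", "NTS_DM"))
  expect_false(any(rk$flagged[!rk$class %in%
                                c("PROTOP_B", "PROTOP_A", "NTS_DM")]))

  # all-null simulation: nothing above the 2-fold report threshold
  cfg0 <- simulation_config(
    seed = 6,
    repeat_classes = dplyr::mutate(default_repeat_classes(), fold = 1))
  c0 <- simulate_repeat_class_counts(cfg0)
  rk0 <- rank_enriched_classes(class_enrichment(c0$chip, c0$input, B = 0))
  expect_false(any(rk0$flagged))
  expect_true(all(abs(rk0$relative_enrichment - 1) < 0.3))

  # relative ranking against a wild type with its own enrichment
  wt <- class_enrichment(c0$chip, c0$input, B = 0)
  rel <- rank_enriched_classes(e, wt)
  expect_equal(rel$class[1], "PROTOP_B")
  expect_true(all(c("wildtype_ratio", "mutant_ratio") %in% names(rel)))
})

test_that("the ratio estimator tightens as read depth grows", {
  # mean absolute error at 1e3, 1e4, 1e5 expected repeat reads decreases
  mae <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    errs <- vapply(1:40, function(s) {
      cfg <- simulation_config(
        seed = 3000 + s * 7 + as.integer(log10(depth)),
        repeat_reads_per_library = depth,
        repeat_classes = tibble::tibble(
          class = c("HOT", "COLD"), length_bp = c(2000, 2000),
          fold = c(4, 1)))
      counts <- simulate_repeat_class_counts(cfg)
      e <- class_enrichment(counts$chip, counts$input, B = 0)
      abs(e$ratio[e$class == "HOT"] - 4)
    }, 0)
    mean(errs)
  }, 0)
  expect_true(all(diff(mae) < 0))
})
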