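test_that("intronic offsets classify as canonical splice, splice region or deep intronic", {
  tx <- toy_tx2()
  # acceptor side of exon 2 (starts at 1501)
  expect_equal(classify_consequence(list(pos = 1499L), tx), "canonical_splice")
  expect_equal(classify_consequence(list(pos = 1500L), tx), "canonical_splice")
  expect_equal(classify_consequence(list(pos = 1498L), tx),
               "splice_region_pm3")
  expect_equal(classify_consequence(list(pos = 1486L), tx), "deep_intronic")
  # donor side of exon 1 (ends at 700)
  expect_equal(classify_consequence(list(pos = 701L), tx), "canonical_splice")
  expect_equal(classify_consequence(list(pos = 703L), tx),
               "splice_region_pm3")
})

test_that("exonic positions outside the CDS are UTRs, on both strands", {
  expect_equal(classify_consequence(list(pos = 1020L), toy_tx3("+")), "utr5")
  expect_equal(classify_consequence(list(pos = 3180L), toy_tx3("+")), "utr3")
  expect_equal(classify_consequence(list(pos = 1020L), toy_tx3("-")), "utr3")
  expect_equal(classify_consequence(list(pos = 3180L), toy_tx3("-")), "utr5")
})

test_that("stop-gains split into NMD-subject and NMD-escaping by the 50-nt rule", {
  tx <- toy_tx3("+")
  # last exon: always escapes
  expect_equal(classify_consequence(list(pos = 3100L, csq = "stop_gained"),
                                    tx),
               "truncating_nmd_escape")
  # penultimate exon, well upstream of the final 50 coding nt: NMD-subject
  expect_equal(classify_consequence(list(pos = 2050L, csq = "stop_gained"),
                                    tx),
               "truncating_nmd")
  # penultimate exon, within its final 50 coding nt (exon 2 ends at 2200)
  expect_equal(classify_consequence(list(pos = 2190L, csq = "stop_gained"),
                                    tx),
               "truncating_nmd_escape")
  # frameshifts follow the same rule; start/stop-loss never escape
  expect_equal(classify_consequence(list(pos = 2050L, csq = "frameshift"),
                                    tx),
               "truncating_nmd")
  expect_equal(classify_consequence(list(pos = 3100L, csq = "stop_lost"), tx),
               "truncating_nmd")
})

test_that("moving a stop-gain across the NMD boundary flips the class and nothing else", {
  tx <- toy_tx3("+")
  # exon 2 spans 2001-2200, all coding; boundary at 50 nt before its 3' end
  upstream <- classify_consequence(list(pos = 2150L, csq = "stop_gained"), tx)
  downstream <- classify_consequence(list(pos = 2151L, csq = "stop_gained"),
                                     tx)
  expect_equal(upstream, "truncating_nmd")
  expect_equal(downstream, "truncating_nmd_escape")
})

test_that("missense and synonymous tokens pass through; variants outside the span error", {
  tx <- toy_tx3("+")
  expect_equal(classify_consequence(list(pos = 2100L, csq = "missense"), tx),
               "missense")
  expect_equal(classify_consequence(list(pos = 2100L, csq = "synonymous"),
                                    tx),
               "synonymous")
  expect_error(classify_consequence(list(pos = 50L), tx), "overlap")
})

test_that("classification is deterministic and total over a transcript scan", {
  tx <- toy_tx3("+")
  positions <- (min(tx$exon_starts) - 3L):(max(tx$exon_ends) + 3L)
  c1 <- vapply(positions, function(p)
    classify_consequence(list(pos = p, csq = "missense"), tx), character(1))
  c2 <- vapply(positions, function(p)
    classify_consequence(list(pos = p, csq = "missense"), tx), character(1))
  expect_identical(c1, c2)
  expect_true(all(c1 %in% consequence_classes()))
})

test_that("the heterozygous VAF window is a closed monotone step on [0.40, 0.60]", {
  expect_true(vaf_in_het_window(0.50))
  expect_true(vaf_in_het_window(0.40))
  expect_true(vaf_in_het_window(0.60))
  expect_false(vaf_in_het_window(0.39))
  expect_false(vaf_in_het_window(0.61))
  expect_error(vaf_in_het_window(1.2), "vaf")
  grid <- seq(0, 1, by = 0.01)
  inside <- vaf_in_het_window(grid)
  expect_identical(inside, grid >= 0.40 & grid <= 0.60)
})

test_that("zygosity inference from VAF never promotes ambiguous fractions", {
  expect_identical(infer_zygosity(c(0.5, 0.99, 0.7, 0.1)),
                   c("het", "hom", "unknown", "unknown"))
})

test_that("adjacent same-VAF calls merge into one delins; distant or discordant calls do not", {
  v <- mk_variants(pos = c(1000L, 1002L), vaf = c(0.48, 0.52))
  m <- merge_adjacent_calls(v, max_gap = 10L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$var_type, "delins")
  expect_equal(m$vaf, 0.50)
  far <- mk_variants(pos = c(1000L, 1500L), vaf = c(0.48, 0.52))
  expect_equal(nrow(merge_adjacent_calls(far, max_gap = 10L)), 2L)
  discordant <- mk_variants(pos = c(1000L, 1002L), vaf = c(0.30, 0.52))
  expect_equal(nrow(merge_adjacent_calls(discordant, max_gap = 10L)), 2L)
  one <- mk_variants(pos = 1000L)
  expect_identical(merge_adjacent_calls(one, 10L), one)
})

test_that("merging is idempotent over randomised call sets", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    v <- mk_variants(pos = sort(sample(1000:1100, n)),
                     vaf = round(stats::runif(n, 0.3, 0.7), 2),
                     var_type = sample(c("SNV", "indel", "delins"), n,
                                       replace = TRUE))
    once <- merge_adjacent_calls(v, max_gap = 10L)
    twice <- merge_adjacent_calls(once, max_gap = 10L)
    expect_identical(twice, once)
    expect_lte(nrow(once), nrow(v))
  }
})

test_that("unsorted input to merge_adjacent_calls is rejected", {
  v <- mk_variants(pos = c(1002L, 1000L))
  expect_error(merge_adjacent_calls(v), "sorted")
})

test_that("variant tables validate ranges and CNV zygosity", {
  expect_error(mk_variants(pos = 1L, vaf = 1.5), "vaf")
  expect_error(mk_variants(pos = 1L, population_af = -0.1), "population_af")
  expect_error(mk_variants(pos = 10L, end = 5L, var_type = "CNV_del"),
               "CNV")
  expect_error(mk_variants(pos = 10L, end = 50L, var_type = "CNV_del",
                           zygosity = "unknown"),
               "zygosity")
  expect_error(panel_table(data.frame(gene = "G", moi = "XLR", chrom = "7")),
               "XLR")
})
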