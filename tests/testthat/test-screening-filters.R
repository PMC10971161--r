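# Strict (L)P filter and VUS extension behaviour; gene G1 is autosomal
# recessive unless noted.

toy_panel <- function() {
  panel_table(data.frame(gene = c("G1", "G2", "GAD", "GX"),
                         moi = c("AR", "AR", "AD", "XLR"),
                         chrom = c("1", "2", "3", "X"),
                         stringsAsFactors = FALSE))
}

test_that("the strict filter retains by knowledge base, novel truncation or splice region", {
  kb <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
              list("1", 1010, "A", "T", "VKGL", "VUS"))
  v <- mk_variants(pos = c(1000L, 1010L, 1020L, 1030L),
                   csq = c("missense", "missense", "stop_gained",
                           "missense"))
  v$csq[4] <- "splice_region"
  cands <- strict_lp_filter(v, kb, NULL)
  expect_setequal(cands$pos, c(1000L, 1020L, 1030L))
  expect_equal(cands$selection_reason[cands$pos == 1000L], "db_lp")
  expect_equal(cands$working_class[cands$pos == 1000L], "LP")
  expect_equal(cands$selection_reason[cands$pos == 1020L],
               "truncating_novel")
  expect_equal(cands$working_class[cands$pos == 1020L], "LP")
  expect_equal(cands$selection_reason[cands$pos == 1030L], "splice_pm3")
  expect_equal(cands$working_class[cands$pos == 1030L], "VUS")
})

test_that("the allele-frequency gate removes common variants regardless of class", {
  kb <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "P"))
  v <- mk_variants(pos = 1000L, population_af = 0.02, csq = "missense")
  expect_equal(nrow(strict_lp_filter(v, kb, NULL)), 0L)
  # straddling the cutoff responds to config (thresholds flow from config)
  v2 <- mk_variants(pos = 1000L, population_af = 0.005, csq = "missense")
  expect_equal(nrow(strict_lp_filter(v2, kb, NULL)), 1L)
  cfg_tight <- pipeline_config(af_cutoff = 0.001)
  expect_equal(nrow(strict_lp_filter(v2, kb, NULL, cfg_tight)), 0L)
})

test_that("UTR variants classed VUS are removed and raw-only variants are never seen", {
  kb <- mk_kb(list("1", 1000, "A", "T", "VKGL", "VUS"))
  utr <- mk_variants(pos = 1000L, csq = "utr5", zygosity = "hom", vaf = 0.99)
  expect_equal(nrow(strict_lp_filter(utr, kb, NULL)), 0L)
  raw <- mk_variants(pos = 1020L, csq = "stop_gained", raw_only = TRUE)
  expect_equal(nrow(strict_lp_filter(raw, mk_kb(), NULL)), 0L)
  no_af <- mk_variants(pos = 1000L)
  no_af$population_af <- NA_real_
  expect_error(strict_lp_filter(no_af, kb, NULL), "population_af")
})

test_that("review decisions exclude, downgrade or confirm candidates", {
  kb <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
              list("1", 1010, "A", "T", "ClinVar", "P"))
  v <- mk_variants(pos = c(1000L, 1010L), csq = "missense")
  cands <- strict_lp_filter(v, kb, NULL)
  expect_identical(apply_review(cands, NULL), cands)
  expect_identical(apply_review(cands, review_table(
    data.frame(variant_key = character(), decision = character()))), cands)
  rv <- review_table(data.frame(variant_key = cands$variant_key[1],
                                decision = "exclude_artefact"))
  expect_equal(nrow(apply_review(cands, rv)), 1L)
  rv2 <- review_table(data.frame(variant_key = cands$variant_key[2],
                                 decision = "downgrade_VUS"))
  out <- apply_review(cands, rv2)
  expect_equal(out$working_class[out$variant_key == cands$variant_key[2]],
               "VUS")
  expect_warning(apply_review(cands, review_table(
    data.frame(variant_key = "9:9:A:T", decision = "keep_P"))),
    "no candidate")
})

test_that("one windowed (L)P heterozygote in a recessive gene pulls in the gene's VUS", {
  kb <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
              list("1", 1050, "G", "C", "VKGL", "VUS"))
  v <- mk_variants(pos = c(1000L, 1050L), ref = c("A", "G"),
                   alt = c("T", "C"), vaf = c(0.5, 0.48),
                   csq = "missense")
  cands <- strict_lp_filter(v, kb, NULL)
  expect_equal(nrow(cands), 1L)
  ext <- vus_extension(cands, v, kb, toy_panel())
  expect_equal(nrow(ext), 2L)
  expect_equal(ext$working_class[ext$pos == 1050L], "VUS")
  expect_equal(ext$selection_reason[ext$pos == 1050L], "vus_extension")
  # rare unlisted non-synonymous variants are eligible too
  v2 <- mk_variants(pos = c(1000L, 1060L), ref = c("A", "G"),
                    alt = c("T", "C"), vaf = c(0.5, 0.52), csq = "missense")
  ext2 <- vus_extension(strict_lp_filter(v2, kb, NULL), v2, kb, toy_panel())
  expect_equal(nrow(ext2), 2L)
  # but synonymous ones are not
  v3 <- mk_variants(pos = c(1000L, 1060L), ref = c("A", "G"),
                    alt = c("T", "C"), vaf = c(0.5, 0.52),
                    csq = c("missense", "synonymous"))
  expect_equal(nrow(vus_extension(strict_lp_filter(v3, kb, NULL), v3, kb,
                                  toy_panel())), 1L)
})

test_that("the VUS extension never triggers for AD genes, homozygous (L)P, or multiple (L)P", {
  kb <- mk_kb(list("3", 1000, "A", "T", "ClinVar", "LP"),
              list("3", 1050, "G", "C", "VKGL", "VUS"))
  # AD gene: no extension
  v_ad <- mk_variants(pos = c(1000L, 1050L), chrom = "3", gene = "GAD",
                      ref = c("A", "G"), alt = c("T", "C"),
                      vaf = c(0.5, 0.5), csq = "missense")
  cands <- strict_lp_filter(v_ad, kb, NULL)
  expect_equal(nrow(vus_extension(cands, v_ad, kb, toy_panel())), 1L)
  # homozygous (L)P: VAF outside the window, no extension
  kb2 <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
               list("1", 1050, "G", "C", "VKGL", "VUS"))
  v_hom <- mk_variants(pos = c(1000L, 1050L), ref = c("A", "G"),
                       alt = c("T", "C"), vaf = c(1.0, 0.5),
                       zygosity = c("hom", "het"), csq = "missense")
  cands2 <- strict_lp_filter(v_hom, kb2, NULL)
  expect_equal(nrow(vus_extension(cands2, v_hom, kb2, toy_panel())), 1L)
  # homozygous VUS with no (L)P in the gene: nothing added
  kb3 <- mk_kb(list("1", 1050, "G", "C", "VKGL", "VUS"))
  v_vus <- mk_variants(pos = 1050L, ref = "G", alt = "C", vaf = 0.99,
                       zygosity = "hom", csq = "missense")
  cands3 <- strict_lp_filter(v_vus, kb3, NULL)
  expect_equal(nrow(cands3), 0L)
  expect_equal(nrow(vus_extension(cands3, v_vus, kb3, toy_panel())), 0L)
  # two (L)P heterozygotes: trigger requires exactly one by default
  kb4 <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
               list("1", 1010, "A", "T", "ClinVar", "LP"),
               list("1", 1050, "G", "C", "VKGL", "VUS"))
  v_two <- mk_variants(pos = c(1000L, 1010L, 1050L),
                       ref = c("A", "A", "G"), alt = c("T", "T", "C"),
                       vaf = 0.5, csq = "missense")
  cands4 <- strict_lp_filter(v_two, kb4, NULL)
  expect_equal(nrow(vus_extension(cands4, v_two, kb4, toy_panel())), 2L)
})

test_that("extension is a monotone superset that leaves the (L)P set unchanged", {
  set.seed(11)
  panel <- toy_panel()
  for (i in 1:15) {
    n <- sample(2:6, 1)
    pos <- sort(sample(seq(1000L, 1100L, by = 2L), n))
    cls <- sample(c("LP", "VUS", "none"), n, replace = TRUE)
    entries <- list()
    for (j in seq_len(n)) if (cls[j] != "none")
      entries[[length(entries) + 1L]] <-
        list("1", pos[j], "A", "T", "ClinVar", cls[j])
    kb <- if (length(entries)) do.call(mk_kb, entries) else mk_kb()
    v <- mk_variants(pos = pos, vaf = sample(c(0.5, 0.45, 0.99), n,
                                             replace = TRUE),
                     csq = "missense")
    cands <- strict_lp_filter(v, kb, NULL)
    ext <- vus_extension(cands, v, kb, panel)
    expect_true(all(cands$variant_key %in% ext$variant_key))
    lp_before <- sort(cands$variant_key[cands$working_class %in%
                                          c("P", "LP")])
    lp_after <- sort(ext$variant_key[ext$working_class %in% c("P", "LP")])
    expect_identical(lp_before, lp_after)
  }
})

test_that("the pipelined strict filter agrees with an independent per-branch checker", {
  set.seed(23)
  tx <- toy_tx3("+")
  txs <- transcript_set(list(tx))
  cfg <- pipeline_config()
  for (i in 1:40) {
    n <- sample(1:6, 1)
    pos <- sort(sample(c(1060:1195, 2001:2200, 3001:3145, 1998:2000), n))
    csq <- sample(c("missense", "stop_gained", "synonymous", "frameshift"),
                  n, replace = TRUE)
    entries <- list()
    for (j in seq_len(n)) {
      cls <- sample(c("P", "LP", "VUS", "B", "none"), 1)
      if (cls != "none")
        entries[[length(entries) + 1L]] <-
          list("1", pos[j], "A", "T", sample(c("ClinVar", "VKGL"), 1), cls)
    }
    kb <- if (length(entries)) do.call(mk_kb, entries) else mk_kb()
    v <- mk_variants(pos = pos, gene = "TOY3", csq = csq,
                     population_af = sample(c(1e-4, 0.05), n, replace = TRUE,
                                            prob = c(0.8, 0.2)),
                     transcript_id = "TX_TOY3.1")
    kept <- strict_lp_filter(v, kb, txs, cfg)
    oracle <- oracle_strict_keep(v, kb, txs, cfg)
    expect_setequal(kept$variant_key, v$variant_key[oracle])
  }
})

test_that("candidate output order is deterministic under input shuffling", {
  kb <- mk_kb(list("1", 1000, "A", "T", "ClinVar", "LP"),
              list("1", 1010, "A", "T", "ClinVar", "P"),
              list("1", 1020, "A", "T", "ClinVar", "LP"))
  v <- mk_variants(pos = c(1000L, 1010L, 1020L), csq = "missense")
  set.seed(3)
  shuffled <- v[sample(nrow(v)), ]
  expect_identical(strict_lp_filter(v, mk_kb(list("1", 1000, "A", "T",
                                                  "ClinVar", "LP"),
                                             list("1", 1010, "A", "T",
                                                  "ClinVar", "P"),
                                             list("1", 1020, "A", "T",
                                                  "ClinVar", "LP")), NULL),
                   strict_lp_filter(shuffled, kb, NULL))
})
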