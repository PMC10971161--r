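test_that("the shipped fixture covers 47 patients with 3 no-data samples per method", {
  fx <- detection_fixture()
  expect_equal(length(unique(fx$fixture$sample_id)), 47L)
  expect_equal(nrow(fx$truth), 47L)
  for (m in c("tNGS", "WES", "WGS")) {
    col <- fx$fixture[[paste0("status_", m)]]
    expect_true(all(col %in% c("LP_surfaced", "VUS_surfaced", "not_surfaced",
                               "no_data")))
    nd <- tapply(col, fx$fixture$sample_id, function(s) all(s == "no_data"))
    expect_equal(sum(nd), 3L)
    expect_equal(replay_detection(fx$fixture, m, "strict")$n_evaluable, 44L)
  }
})

test_that("replay reproduces the published per-method detection counts", {
  fx <- detection_fixture()$fixture
  strict <- sapply(c("tNGS", "WES", "WGS"), function(m)
    unlist(replay_detection(fx, m, "strict")[c("tp", "fn")]))
  expect_equal(unname(strict["tp", ]), c(33L, 31L, 30L))
  expect_equal(unname(strict["fn", ]), c(11L, 13L, 14L))
  ext <- sapply(c("tNGS", "WGS"), function(m)
    unlist(replay_detection(fx, m, "extended")[c("tp", "fn")]))
  expect_equal(unname(ext["tp", ]), c(40L, 38L))
  expect_equal(unname(ext["fn", ]), c(4L, 6L))
})

test_that("extended replay dominates strict and the evaluable set is strategy-invariant", {
  fx <- detection_fixture()$fixture
  set.seed(31)
  subsets <- c(list(unique(fx$sample_id)),
               lapply(1:5, function(i) sample(unique(fx$sample_id),
                                              sample(5:40, 1))))
  for (m in c("tNGS", "WES", "WGS")) for (ids in subsets) {
    sub <- fx[fx$sample_id %in% ids, ]
    s <- replay_detection(sub, m, "strict")
    e <- replay_detection(sub, m, "extended")
    expect_gte(e$tp, s$tp)
    expect_lte(e$fn, s$fn)
    expect_equal(s$tp + s$fn, e$tp + e$fn)
    expect_true(all(attr(s, "tp_samples") %in% attr(e, "tp_samples")))
  }
})

test_that("false-negative reports carry the annotated miss reasons", {
  fx <- detection_fixture()
  wgs <- fn_cause_report(fx$fixture, fx$fn_causes, "WGS", "extended")
  expect_setequal(wgs$sample_id, c("S03", "S06", "S30", "S31", "S34", "S36"))
  expect_equal(wgs$cause[wgs$sample_id == "S03"],
               "Low coverage and pseudogene")
  expect_equal(wgs$cause[wgs$sample_id == "S31"],
               "Low coverage and pseudogene")
  tngs <- fn_cause_report(fx$fixture, fx$fn_causes, "tNGS", "extended")
  expect_true("S39" %in% tngs$sample_id)
  expect_match(tngs$cause[tngs$sample_id == "S30"], "hom. VUS", fixed = TRUE)
  # a sample with every variant surfaced yields an empty report
  clean <- fx$fixture[fx$fixture$sample_id == "S01", ]
  expect_equal(nrow(fn_cause_report(clean, fx$fn_causes, "tNGS", "strict")),
               0L)
})

test_that("cohort scoring maps roles and diagnosis genes onto the confusion matrix", {
  panel <- panel_table(data.frame(gene = c("G1", "G2"), moi = c("AR", "AR"),
                                  chrom = c("1", "2"),
                                  stringsAsFactors = FALSE))
  # patient positive in the diagnosis gene, patient positive elsewhere,
  # negative control
  cands <- rbind(mk_cands(c("LP", "LP"), "het", gene = "G1",
                          sample_id = "P1"),
                 mk_cands(c("LP", "LP"), "het", gene = "G1",
                          sample_id = "P2"))
  truth <- truth_table(data.frame(
    sample_id = c("P1", "P2", "C1"),
    cohort_role = c("patient", "patient", "control"),
    diagnosis_gene = c("G1", "G2", NA), stringsAsFactors = FALSE))
  res <- screen_cohort(cands, panel, "strict",
                       sample_ids = c("P1", "P2", "C1"))
  cc <- score_cohort(res, truth)
  expect_equal(cc$tp, 1L)  # P1
  expect_equal(cc$fn, 1L)  # P2: positive in the wrong gene
  expect_equal(cc$tn, 1L)
  expect_equal(cc$fp, 0L)
  expect_equal(attr(cc, "incidentals")$sample_id, "P2")
  # a result without a truth record is an error
  expect_error(score_cohort(res, truth[1:2, ]), "truth")
  # empty cohort scores all zero
  cc0 <- score_cohort(list(), truth[0, ])
  expect_equal(unlist(cc0[c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 0L, fn = 0L, tn = 0L))
})

test_that("fixture replay and the MOI screen agree on hand-transcribed samples", {
  # reconstruct variant records for five samples whose replay outcome must
  # match a full pipeline run: S01 (hom splice LP), S02 (compound het),
  # S07 (AD het), S08 (het LP + VUS), S30 (hom VUS)
  panel <- default_panel()
  kb <- mk_kb(list("3", 100, "A", "G", "ClinVar", "LP"),   # SLC2A2 splice
              list("19", 200, "C", "T", "ClinVar", "LP"),  # GCDH c.219del
              list("19", 210, "G", "A", "ClinVar", "P"),   # GCDH c.482G>A
              list("1", 300, "C", "G", "ClinVar", "P"),    # SLC2A1 splice
              list("13", 400, "G", "C", "VKGL", "VUS"),    # PCCA c.625G>C
              list("13", 410, "T", "C", "ClinVar", "LP"),  # PCCA c.923dup
              list("15", 500, "C", "T", "VKGL", "VUS"))    # ETFA c.-40G>A
  v <- rbind(
    mk_variants(pos = 100L, sample_id = "S01", chrom = "3", gene = "SLC2A2",
                ref = "A", alt = "G", vaf = 0.99, zygosity = "hom",
                csq = "splice_acceptor"),
    mk_variants(pos = c(200L, 210L), sample_id = "S02", chrom = "19",
                gene = "GCDH", ref = c("C", "G"), alt = c("T", "A"),
                csq = c("frameshift", "missense")),
    mk_variants(pos = 300L, sample_id = "S07", chrom = "1", gene = "SLC2A1",
                ref = "C", alt = "G", csq = "splice_acceptor"),
    mk_variants(pos = c(400L, 410L), sample_id = "S08", chrom = "13",
                gene = "PCCA", ref = c("G", "T"), alt = c("C", "C"),
                csq = c("missense", "frameshift")),
    mk_variants(pos = 500L, sample_id = "S30", chrom = "15", gene = "ETFA",
                ref = "C", alt = "T", vaf = 0.99, zygosity = "hom",
                csq = "utr5"))
  ids <- c("S01", "S02", "S07", "S08", "S30")
  fx <- detection_fixture()$fixture
  fx <- fx[fx$sample_id %in% ids, ]
  for (strategy in c("strict", "extended")) {
    pipe <- screen_pipeline(v, panel, kb, NULL, config = pipeline_config(),
                            strategy = strategy, sample_ids = ids)
    pos_pipe <- vapply(pipe$results, function(r) r$overall == "positive",
                       logical(1))
    names(pos_pipe) <- vapply(pipe$results, `[[`, character(1), "sample_id")
    counts <- replay_detection(fx, "tNGS", strategy)
    pos_replay <- ids %in% attr(counts, "tp_samples")
    expect_equal(unname(pos_pipe[ids]), pos_replay, info = strategy)
  }
})
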