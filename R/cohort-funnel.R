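# Background-cohort assessment funnel: staged counts (no-SNV, no-(L)P,
# MOI-fit pre/post review, single-(L)P-het, VUS-extension fit pre/post
# review) with an auditable per-individual stage assignment and review queue.

FUNNEL_STAGES <- c("no_snv", "no_lp", "moi_fit", "single_lp_het",
                   "vus_moi_fit", "other")

#' Run the background-cohort assessment funnel
#'
#' Stages, applied in order per individual: (1) individuals without any
#' small variant (SNV/indel, optionally toggled) in the coding and splicing
#' region (CDS +/- the splice window of the designated transcript) of a panel
#' gene; (2) the strict (L)P filter; individuals with no (likely) pathogenic
#' candidate; (3) mode-of-inheritance fit via strict screening (pre-review);
#' (4) review exclusions re-screened (post-review); (5) among non-fit
#' individuals, those with exactly one (L)P, heterozygous VAF window, in an
#' AR/XLR gene; (6) the VUS extension plus extended screening (pre-review);
#' (7) review again (post-review). Counts are over individuals and partition
#' the cohort (`no_snv + no_lp + moi_fit + single_lp_het + vus_moi_fit +
#' other = total`, with the MOI-fit buckets taken pre-review).
#'
#' @param variants Variant table for the whole cohort (panel genes only;
#'   variants in non-panel genes are an error).
#' @param panel [panel_table()].
#' @param kb [knowledge_base()] table.
#' @param transcripts [transcript_set()] or `NULL` (consequence from `csq`).
#' @param review Optional [review_table()].
#' @param config [pipeline_config()].
#' @param sample_ids Cohort universe; defaults to samples seen in `variants`
#'   (supply explicitly so variant-free individuals are counted).
#' @param include_indels Count indels alongside SNVs in the first stage
#'   (default TRUE; the printed funnel names SNVs but small indels were
#'   analysed throughout).
#' @return List of class `funnel_result`: `counts` (list), `stage_of`
#'   (named character vector per individual), `review_queue` (data frame),
#'   `survivors` (list with `lp_moi_fit` and `vus_extension` sample ids),
#'   `audit` (data frame of per-stage denominators).
#' @export
run_funnel <- function(variants, panel, kb, transcripts = NULL, review = NULL,
                       config = pipeline_config(), sample_ids = NULL,
                       include_indels = TRUE) {
  bad <- setdiff(unique(variants$gene), panel$gene)
  if (length(bad))
    stop("variants in non-panel gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  total <- length(sample_ids)
  if (!"consequence" %in% names(variants))
    variants <- annotate_consequences(variants, transcripts,
                                      config$nmd_rule_nt, config$splice_window)
  stage_of <- setNames(rep(NA_character_, total), sample_ids)

  # stage 1: any small variant in the coding + splicing region
  small_types <- if (include_indels) c("SNV", "indel", "delins") else "SNV"
  in_region <- variants$var_type %in% small_types &
    !variants$raw_only &
    !is.na(variants$consequence) &
    !variants$consequence %in% c("utr5", "utr3", "deep_intronic")
  snv_samples <- unique(variants$sample_id[in_region])
  stage_of[setdiff(sample_ids, snv_samples)] <- "no_snv"

  # stage 2: strict filter; (L)P presence
  cands <- strict_lp_filter(variants[in_region, , drop = FALSE], kb,
                            transcripts, config)
  lp_cands <- cands[cands$working_class %in% c("P", "LP"), , drop = FALSE]
  has_lp <- unique(lp_cands$sample_id)
  stage_of[is.na(stage_of) & !sample_ids %in% has_lp] <- "no_lp"

  # stage 3/4: MOI fit, pre- and post-review (strict strategy)
  open_ids <- sample_ids[is.na(stage_of)]
  res_pre <- screen_cohort(cands, panel, "strict", sample_ids = open_ids)
  pos_pre <- vapply(res_pre, function(r) r$overall == "positive", logical(1))
  moi_fit_pre <- open_ids[pos_pre]
  cands_rev <- apply_review(cands, review)
  res_post <- screen_cohort(cands_rev, panel, "strict",
                            sample_ids = moi_fit_pre)
  moi_fit_post <- moi_fit_pre[vapply(res_post, function(r)
    r$overall == "positive", logical(1))]
  stage_of[moi_fit_pre] <- "moi_fit"

  # stage 5: single (L)P het in the VAF window, AR/XLR gene, among non-fit
  open_ids <- sample_ids[is.na(stage_of)]
  lp_post <- cands_rev[cands_rev$working_class %in% c("P", "LP"), ,
                       drop = FALSE]
  lp_open <- lp_post[lp_post$sample_id %in% open_ids, , drop = FALSE]
  single <- character()
  if (nrow(lp_open)) {
    cnt <- table(lp_open$sample_id)
    one <- names(cnt)[cnt == 1L]
    rows <- lp_open[lp_open$sample_id %in% one, , drop = FALSE]
    moi <- panel$moi[match(rows$gene, panel$gene)]
    ok <- moi %in% c("AR", "XLR") &
      vaf_in_het_window(rows$vaf, config$vaf_window)
    single <- rows$sample_id[ok]
  }
  stage_of[single] <- "single_lp_het"

  # stage 6/7: VUS extension among single-het individuals
  vus_fit_pre <- character(); vus_fit_post <- character()
  if (length(single)) {
    sub_cands <- cands_rev[cands_rev$sample_id %in% single, , drop = FALSE]
    sub_vars <- variants[variants$sample_id %in% single, , drop = FALSE]
    sub_vars <- sub_vars[sub_vars$var_type %in% small_types &
                           !sub_vars$raw_only, , drop = FALSE]
    ext <- vus_extension(sub_cands, sub_vars, kb, panel, config)
    res_ext <- screen_cohort(ext, panel, "extended", sample_ids = single)
    vus_fit_pre <- single[vapply(res_ext, function(r)
      r$overall == "positive", logical(1))]
    ext_rev <- apply_review(ext, review)
    res_ext_post <- screen_cohort(ext_rev, panel, "extended",
                                  sample_ids = vus_fit_pre)
    vus_fit_post <- vus_fit_pre[vapply(res_ext_post, function(r)
      r$overall == "positive", logical(1))]
  }
  stage_of[vus_fit_pre] <- "vus_moi_fit"
  stage_of[is.na(stage_of)] <- "other"

  counts <- list(total = total,
                 no_snv = sum(stage_of == "no_snv"),
                 no_lp = sum(stage_of == "no_lp"),
                 moi_fit_prereview = length(moi_fit_pre),
                 moi_fit_postreview = length(moi_fit_post),
                 single_lp_het = sum(stage_of %in%
                                       c("single_lp_het", "vus_moi_fit")),
                 vus_moi_fit_prereview = length(vus_fit_pre),
                 vus_moi_fit_postreview = length(vus_fit_post),
                 other = sum(stage_of == "other"))

  queue_rows <- list()
  queue_add <- function(ids, stage, source) {
    for (sid in ids) {
      rows <- source[source$sample_id == sid, , drop = FALSE]
      for (g in unique(rows$gene))
        queue_rows[[length(queue_rows) + 1L]] <<- data.frame(
          individual_id = sid, gene = g,
          variant_keys = paste(rows$variant_key[rows$gene == g],
                               collapse = ","),
          stage = stage, stringsAsFactors = FALSE)
    }
  }
  queue_add(moi_fit_pre, "lp_moi_fit", cands)
  if (length(vus_fit_pre)) {
    sub_cands <- cands_rev[cands_rev$sample_id %in% single, , drop = FALSE]
    sub_vars <- variants[variants$sample_id %in% single, , drop = FALSE]
    sub_vars <- sub_vars[sub_vars$var_type %in% small_types &
                           !sub_vars$raw_only, , drop = FALSE]
    ext <- vus_extension(sub_cands, sub_vars, kb, panel, config)
    queue_add(vus_fit_pre, "vus_extension", ext)
  }
  review_queue <- if (length(queue_rows)) do.call(rbind, queue_rows) else
    data.frame(individual_id = character(), gene = character(),
               variant_keys = character(), stage = character(),
               stringsAsFactors = FALSE)

  # the printed funnel divides every stage by the cohort total, although the
  # no-(L)P stage is evaluated among individuals with SNVs; report both
  audit <- data.frame(
    stage = c("no_lp_of_total", "no_lp_of_with_snv"),
    numerator = counts$no_lp,
    denominator = c(total, total - counts$no_snv),
    stringsAsFactors = FALSE)

  structure(list(counts = counts, stage_of = stage_of,
                 review_queue = review_queue,
                 survivors = list(lp_moi_fit = moi_fit_post,
                                  vus_extension = vus_fit_post),
                 audit = audit),
            class = "funnel_result")
}

#' Render funnel counts as a table with whole-percent shares
#'
#' Percentages are computed against the cohort total and rounded to whole
#' percent; counts remain the source of truth.
#'
#' @param counts The `counts` element of a [run_funnel()] result (or a
#'   `funnel_result`).
#' @return Data frame with `stage`, `count`, `percent` (e.g. `"7%"`).
#' @export
funnel_report <- function(counts) {
  if (inherits(counts, "funnel_result")) counts <- counts$counts
  if (is.null(counts$total) || counts$total == 0)
    stop("funnel total is zero", call. = FALSE)
  stages <- c("total", "no_snv", "no_lp", "moi_fit_prereview",
              "moi_fit_postreview", "single_lp_het", "vus_moi_fit_prereview",
              "vus_moi_fit_postreview", "other")
  cnt <- vapply(stages, function(s) as.integer(counts[[s]]), integer(1))
  data.frame(stage = stages, count = cnt,
             percent = paste0(round(100 * cnt / counts$total), "%"),
             stringsAsFactors = FALSE)
}
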