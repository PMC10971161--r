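#' nbscreen: variant filtering and interpretation for NGS-based newborn
#' screening
#'
#' Implements a strict (likely)-pathogenic variant filter, a conditional
#' VUS-extension filter, mode-of-inheritance screening calls, carriership
#' detection, a background-cohort assessment funnel, confusion-matrix outcome
#' scoring, and a synthetic-cohort generator for testing the whole pipeline
#' without patient data.
#'
#' @keywords internal
"_PACKAGE"

#' Shipped inherited-metabolic-disorder gene panel
#'
#' The default panel bundles the genes appearing in the package's detection
#' fixture (plus CPT1A), with literature-derived modes of inheritance:
#' SLC2A1 is autosomal dominant, OTC and ABCD1 X-linked recessive, all other
#' genes autosomal recessive.
#'
#' @return A [panel_table()].
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_imd.tsv", package = "nbscreen")
  panel_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Run the full screening pipeline on a cohort
#'
#' Convenience wrapper: strict (L)P filter, review, optional VUS extension
#' (for the extended strategy), mode-of-inheritance screening and carriership
#' detection.
#'
#' @param variants [variant_table()] for the cohort (panel genes only).
#' @param panel [panel_table()].
#' @param kb [knowledge_base()] table.
#' @param transcripts [transcript_set()] or `NULL`.
#' @param review Optional [review_table()].
#' @param config [pipeline_config()].
#' @param strategy `"strict"` or `"extended"`; defaults to the config value.
#' @param sample_ids Sample universe (so variant-free samples are screened
#'   negative); defaults to samples seen in `variants`.
#' @return List with `results` (screen results), `candidates` (the final
#'   candidate table), and `carrierships`.
#' @export
screen_pipeline <- function(variants, panel, kb, transcripts = NULL,
                            review = NULL, config = pipeline_config(),
                            strategy = NULL, sample_ids = NULL) {
  if (is.null(strategy)) strategy <- config$strategy
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  cands <- strict_lp_filter(variants, kb, transcripts, config)
  cands <- apply_review(cands, review)
  if (strategy == "extended")
    cands <- vus_extension(cands, variants, kb, panel, config)
  results <- screen_cohort(cands, panel, strategy, sample_ids = sample_ids)
  list(results = results, candidates = cands,
       carrierships = detect_carriership(results, config$vaf_window))
}
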