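# The two variant-selection strategies: the strict (likely)-pathogenic filter
# and the conditional VUS extension, plus the review-decision hook that stands
# in for clinical-geneticist ACMG review.

SELECTION_REASONS <- c("db_lp", "truncating_novel", "splice_pm3",
                       "vus_extension")
REVIEW_DECISIONS <- c("keep_P", "keep_LP", "downgrade_VUS", "exclude_artefact",
                      "exclude_cis", "exclude_irrelevant")

#' Strict (likely)-pathogenic variant filter
#'
#' Retains a variant iff its population allele frequency is below `af_cutoff`
#' (strict `<`) and at least one branch applies: (a) the knowledge base
#' conclusively classes it (likely) pathogenic; (b) it is truncating
#' (NMD-subject premature stop, start/stop-loss, canonical splice site, or a
#' gene-disrupting CNV deletion) and absent from all knowledge bases; (c) it lies at an intronic splice position
#' within +/-3 bp of an exon boundary. Variants only present in raw data
#' (`raw_only`) were dropped upstream and are never seen by this filter.
#' Retained variants get a `selection_reason` (first matching branch in the
#' order a, b, c) and a default `working_class`: the knowledge-base class for
#' branch (a), LP for novel truncating, VUS for splice-region candidates.
#'
#' @param variants Variant data frame ([variant_table()]), restricted to panel
#'   genes, with `population_af` present for every row.
#' @param kb [knowledge_base()] table.
#' @param transcripts [transcript_set()] (or `NULL` to rely on `csq` tokens).
#' @param config [pipeline_config()]; `af_cutoff`, `nmd_rule_nt` and
#'   `splice_window` are consumed here.
#' @return Candidate data frame: retained variant rows plus `consequence`,
#'   `selection_reason`, `working_class`, `reviewed`, sorted by
#'   (sample, chrom, pos, alt).
#' @export
strict_lp_filter <- function(variants, kb, transcripts = NULL,
                             config = pipeline_config()) {
  if (any(is.na(variants$population_af)))
    stop("population_af missing for one or more variants", call. = FALSE)
  v <- variants[!variants$raw_only, , drop = FALSE]
  if (!"consequence" %in% names(v))
    v <- annotate_consequences(v, transcripts,
                               nmd_rule_nt = config$nmd_rule_nt,
                               splice_window = config$splice_window)
  kv <- kb_verdicts(v, kb)
  af_ok <- v$population_af < config$af_cutoff
  a <- kv$verdict == "LP_or_P"
  b <- (!is.na(v$consequence) &
          v$consequence %in% c("truncating_nmd", "canonical_splice") |
          v$var_type == "CNV_del") &
    kv$verdict == "none"
  c_ <- !is.na(v$consequence) & v$consequence == "splice_region_pm3"
  keep <- af_ok & (a | b | c_)
  out <- v[keep, , drop = FALSE]
  reason <- ifelse(a[keep], "db_lp",
                   ifelse(b[keep], "truncating_novel", "splice_pm3"))
  wc <- ifelse(a[keep], kv$best_class[keep],
               ifelse(b[keep], "LP", "VUS"))
  out$selection_reason <- reason
  out$working_class <- wc
  out$reviewed <- rep(FALSE, nrow(out))
  ord <- order(out$sample_id, out$chrom, out$pos, out$alt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct/validate a review-decision table
#'
#' One decision per variant key: keep at a stated class, downgrade to VUS, or
#' exclude (cis-called deletion-insertion fragments, sequencing artefacts,
#' variants irrelevant on prediction/literature grounds).
#'
#' @param df Data frame with columns `variant_key`, `decision` and optional
#'   `note`.
#' @return Validated data frame.
#' @export
review_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("variant_key", "decision") %in% names(df)))
    stop("review table needs variant_key and decision columns", call. = FALSE)
  if (!"note" %in% names(df)) df$note <- rep(NA_character_, nrow(df))
  if (any(!df$decision %in% REVIEW_DECISIONS))
    stop("unknown review decision token", call. = FALSE)
  if (anyDuplicated(df$variant_key))
    stop("more than one decision for a variant key", call. = FALSE)
  df
}

#' Load a review-decision table from TSV
#'
#' @param path TSV with header `variant_key decision note`.
#' @return Validated [review_table()].
#' @export
load_review_table <- function(path) {
  review_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Apply review decisions to a candidate list
#'
#' Exclusion decisions remove the candidate; `downgrade_VUS` sets the working
#' class to VUS; `keep_P`/`keep_LP` set the stated class. Unreviewed
#' candidates keep their default class. Decisions whose key matches no
#' candidate produce a warning only (review tables may be cohort-global).
#'
#' @param candidates Output of [strict_lp_filter()] (or [vus_extension()]).
#' @param review A [review_table()] or `NULL` for no review.
#' @return Candidate data frame after review.
#' @export
apply_review <- function(candidates, review = NULL) {
  if (is.null(review) || !nrow(review)) return(candidates)
  review <- review_table(review)
  unused <- setdiff(review$variant_key, candidates$variant_key)
  if (length(unused))
    warning(length(unused), " review decision(s) matched no candidate",
            call. = FALSE)
  i <- match(candidates$variant_key, review$variant_key)
  dec <- ifelse(is.na(i), NA_character_, review$decision[i])
  drop <- !is.na(dec) & dec %in% c("exclude_artefact", "exclude_cis",
                                   "exclude_irrelevant")
  out <- candidates[!drop, , drop = FALSE]
  dec <- dec[!drop]
  out$working_class[!is.na(dec) & dec == "downgrade_VUS"] <- "VUS"
  out$working_class[!is.na(dec) & dec == "keep_P"] <- "P"
  out$working_class[!is.na(dec) & dec == "keep_LP"] <- "LP"
  out$reviewed <- out$reviewed | !is.na(dec)
  rownames(out) <- NULL
  out
}

#' Conditional VUS extension of the strict filter
#'
#' For each sample and each autosomal-recessive or X-linked-recessive panel
#' gene holding exactly one (likely) pathogenic candidate whose VAF lies in
#' the heterozygous 40-60% window, all additional variants of that sample in
#' that gene that are either classed VUS in the knowledge base, or absent from
#' it but rare (`population_af < af_cutoff`) and not synonymous, are appended
#' as working-class VUS candidates. The output is a superset of the input; the
#' set of (L)P candidates is unchanged. No VUS is added for AD genes or when
#' zero or two-plus (L)P candidates sit in the gene (set
#' `vus_trigger_mode = "at_least_one"` to relax the trigger).
#'
#' @param candidates Post-review output of [strict_lp_filter()].
#' @param all_variants Full variant table for the same samples (the pool the
#'   VUS are drawn from).
#' @param kb [knowledge_base()] table.
#' @param panel [panel_table()].
#' @param config [pipeline_config()].
#' @return Candidate data frame including the appended VUS rows.
#' @export
vus_extension <- function(candidates, all_variants, kb, panel,
                          config = pipeline_config()) {
  if (!nrow(candidates)) return(candidates)
  moi <- panel$moi[match(candidates$gene, panel$gene)]
  is_lp <- candidates$working_class %in% c("P", "LP")
  grp <- paste(candidates$sample_id, candidates$gene, sep = "\r")
  lp_in_window <- is_lp & vaf_in_het_window(candidates$vaf, config$vaf_window)
  n_lp <- tapply(is_lp, grp, sum)
  n_lp_win <- tapply(lp_in_window, grp, sum)
  trigger_n <- n_lp[n_lp > 0]
  groups <- names(trigger_n)
  triggered <- character()
  for (g in groups) {
    gene <- sub("^.*\r", "", g)
    m <- panel$moi[match(gene, panel$gene)]
    if (is.na(m) || !m %in% c("AR", "XLR")) next
    ok_count <- if (identical(config$vus_trigger_mode, "at_least_one"))
      n_lp[[g]] >= 1L else n_lp[[g]] == 1L
    # the trigger (L)P itself must sit in the heterozygous VAF window
    if (ok_count && n_lp_win[[g]] == n_lp[[g]] && n_lp_win[[g]] >= 1L)
      triggered <- c(triggered, g)
  }
  if (!length(triggered)) return(candidates)
  av <- all_variants[!all_variants$raw_only &
                       !all_variants$var_type %in% c("CNV_del", "CNV_dup"), ,
                     drop = FALSE]
  if (!"consequence" %in% names(av))
    av <- annotate_consequences(av, NULL, config$nmd_rule_nt,
                                config$splice_window)
  av_grp <- paste(av$sample_id, av$gene, sep = "\r")
  pool <- av[av_grp %in% triggered, , drop = FALSE]
  if (nrow(pool)) {
    already <- paste(pool$sample_id, pool$variant_key, sep = "\r") %in%
      paste(candidates$sample_id, candidates$variant_key, sep = "\r")
    pool <- pool[!already, , drop = FALSE]
  }
  if (nrow(pool)) {
    kv <- kb_verdicts(pool, kb)
    eligible <- kv$verdict == "VUS" |
      (kv$verdict == "none" & pool$population_af < config$af_cutoff &
         (is.na(pool$consequence) | pool$consequence != "synonymous"))
    pool <- pool[eligible, , drop = FALSE]
  }
  if (!nrow(pool)) return(candidates)
  pool$selection_reason <- "vus_extension"
  pool$working_class <- "VUS"
  pool$reviewed <- FALSE
  out <- rbind(candidates[, names(pool)], pool)
  ord <- order(out$sample_id, out$chrom, out$pos, out$alt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
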