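# Mode-of-inheritance screening: turn a sample's classified candidates into
# per-gene and per-sample calls (positive / carrier / negative), including
# compound-heterozygote, hemizygous and CNV-allele logic, and carriership
# detection.

#' Pathogenic allele count for one gene's candidates
#'
#' Counts pathogenic alleles among the supplied candidates (assumed to share
#' one gene): homozygous contributes 2, heterozygous 1, hemizygous 2 (no
#' second allele is present). A CNV deletion contributes per its zygosity
#' (het 1, hom 2); when a CNV deletion co-occurs with a hemizygous small
#' variant, the deletion is the missing allele, so the hemizygous variant
#' contributes 1 instead of 2. Variants flagged in cis collectively count
#' once. Two heterozygous variants are assumed in trans unless flagged.
#'
#' @param variants Candidate data frame for one gene.
#' @return Integer pathogenic-allele count.
#' @export
allele_count <- function(variants) {
  if (!nrow(variants)) return(0L)
  if (length(unique(variants$gene)) > 1L)
    stop("allele_count expects variants from one gene", call. = FALSE)
  has_cnv_del <- any(variants$var_type == "CNV_del")
  per <- integer(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    z <- variants$zygosity[i]
    if (variants$var_type[i] == "CNV_dup") { per[i] <- 0L; next }
    if (variants$var_type[i] == "CNV_del") {
      per[i] <- switch(z, hom = 2L, hemi = 2L, 1L)
      next
    }
    per[i] <- switch(z,
                     hom = 2L,
                     hemi = if (has_cnv_del) 1L else 2L,
                     het = 1L,
                     0L)
  }
  cis <- variants$in_cis %in% TRUE
  as.integer(sum(per[!cis]) + per_cis_contribution(per[cis]))
}

# A group of in-cis variants sits on one haplotype: it contributes a single
# allele (or two if the shared haplotype is homozygous).
per_cis_contribution <- function(per) {
  if (!length(per)) return(0L)
  if (any(per >= 2L)) 2L else 1L
}

#' Screen one gene under the mode of inheritance
#'
#' AD: any (L)P variant is positive. AR: a pathogenic-allele count of 2+ from
#' (L)P variants is positive; under the extended strategy exactly one
#' heterozygous (L)P plus at least one heterozygous VUS is also positive;
#' exactly one heterozygous (L)P otherwise makes a carrier. XLR: hemizygous
#' or homozygous (L)P is positive, heterozygous (L)P is a carrier, and the
#' extended rule applies as for AR. Everything else is negative.
#'
#' @param gene Gene symbol.
#' @param moi `"AD"`, `"AR"` or `"XLR"`.
#' @param lp_variants Candidate rows with working class P/LP in this gene.
#' @param vus_variants Candidate rows with working class VUS in this gene.
#' @param strategy `"strict"` or `"extended"`.
#' @return List of class `gene_finding`: `gene`, `moi`, `call`, `lp_variants`,
#'   `vus_variants`, `n_lp_alleles`.
#' @export
screen_gene <- function(gene, moi, lp_variants, vus_variants,
                        strategy = c("strict", "extended")) {
  strategy <- match.arg(strategy)
  if (!moi %in% MOI_VALUES) stop("unknown MOI: ", moi, call. = FALSE)
  n_alleles <- allele_count(lp_variants)
  n_lp <- nrow(lp_variants)
  het_lp <- sum(lp_variants$zygosity == "het" |
                  (lp_variants$var_type == "CNV_del" &
                     lp_variants$zygosity == "het"))
  hom_or_hemi <- any(lp_variants$zygosity %in% c("hom", "hemi") &
                       !lp_variants$var_type %in% c("CNV_dup"))
  het_vus <- sum(vus_variants$zygosity == "het")
  call <- "negative"
  if (moi == "AD") {
    if (n_lp >= 1L) call <- "positive"
  } else if (moi == "AR") {
    if (n_alleles >= 2L) call <- "positive"
    else if (n_lp == 1L && het_lp == 1L) {
      call <- if (strategy == "extended" && het_vus >= 1L) "positive"
              else "carrier"
    }
  } else { # XLR
    if (hom_or_hemi || n_alleles >= 2L) call <- "positive"
    else if (n_lp == 1L && het_lp == 1L) {
      call <- if (strategy == "extended" && het_vus >= 1L) "positive"
              else "carrier"
    }
  }
  structure(list(gene = gene, moi = moi, call = call,
                 lp_variants = lp_variants, vus_variants = vus_variants,
                 n_lp_alleles = n_alleles),
            class = "gene_finding")
}

#' Screen a cohort of candidate variants
#'
#' Groups candidates per sample and gene, screens each gene under its panel
#' mode of inheritance and assembles one screen result per sample. Samples
#' listed in `sample_ids` but holding no candidates are negative.
#'
#' @param candidates Candidate data frame (post-filter, post-review, and
#'   post-[vus_extension()] when screening the extended strategy).
#' @param panel [panel_table()]; candidates in genes absent from the panel are
#'   an error (the virtual panel was violated upstream).
#' @param strategy `"strict"` or `"extended"`.
#' @param sample_ids Sample universe; defaults to samples seen in
#'   `candidates`.
#' @return List of `screen_result` objects: `sample_id`, `strategy`,
#'   `overall` (`"positive"`/`"negative"`), `findings`, `carrierships`.
#' @export
screen_cohort <- function(candidates, panel, strategy = c("strict", "extended"),
                          sample_ids = NULL) {
  strategy <- match.arg(strategy)
  if (nrow(candidates)) {
    bad <- setdiff(unique(candidates$gene), panel$gene)
    if (length(bad))
      stop("candidate gene(s) not on the panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- unique(candidates$sample_id)
  by_sample <- split(candidates, factor(candidates$sample_id,
                                        levels = sample_ids))
  lapply(sample_ids, function(sid) {
    cand <- by_sample[[sid]]
    findings <- list()
    if (!is.null(cand) && nrow(cand)) {
      for (g in unique(cand$gene)) {
        rows <- cand[cand$gene == g, , drop = FALSE]
        moi <- panel$moi[match(g, panel$gene)]
        lp <- rows[rows$working_class %in% c("P", "LP"), , drop = FALSE]
        vus <- rows[rows$working_class == "VUS", , drop = FALSE]
        findings[[g]] <- screen_gene(g, moi, lp, vus, strategy)
      }
    }
    calls <- vapply(findings, `[[`, character(1), "call")
    res <- structure(list(sample_id = sid, strategy = strategy,
                          overall = if (any(calls == "positive")) "positive"
                                    else "negative",
                          findings = findings),
                     class = "screen_result")
    res
  })
}

#' Detect carrierships across screen results
#'
#' A carriership is one heterozygous (likely) pathogenic variant with a VAF in
#' the heterozygous window in an autosomal-recessive gene, in any sample.
#' Emitted only for genes called carrier (never for genes already positive);
#' carrierships are computed but flagged non-reportable by default, since
#' carrier status is outside the scope of newborn screening.
#'
#' @param results List of screen results from [screen_cohort()].
#' @param vaf_window Heterozygous VAF window (default 40-60%).
#' @return Data frame `sample_id`, `gene`, `variant_key`, `vaf`, `reportable`.
#' @export
detect_carriership <- function(results, vaf_window = c(0.40, 0.60)) {
  rows <- list()
  for (res in results) {
    for (f in res$findings) {
      if (f$call != "carrier" || f$moi != "AR") next
      lp <- f$lp_variants
      lp <- lp[vaf_in_het_window(lp$vaf, vaf_window), , drop = FALSE]
      if (!nrow(lp)) next
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = res$sample_id, gene = f$gene,
                   variant_key = lp$variant_key, vaf = lp$vaf,
                   reportable = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), gene = character(),
                      variant_key = character(), vaf = numeric(),
                      reportable = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten screen results to a data frame
#'
#' @param results List of screen results from [screen_cohort()].
#' @return Data frame with one row per (sample, gene) finding plus
#'   sample-level `overall`; samples without findings get a single row with
#'   `gene = NA`.
#' @export
screen_results_table <- function(results) {
  rows <- lapply(results, function(res) {
    if (!length(res$findings))
      return(data.frame(sample_id = res$sample_id, strategy = res$strategy,
                        overall = res$overall, gene = NA_character_,
                        moi = NA_character_, call = NA_character_,
                        n_lp = 0L, n_vus = 0L, stringsAsFactors = FALSE))
    do.call(rbind, lapply(res$findings, function(f)
      data.frame(sample_id = res$sample_id, strategy = res$strategy,
                 overall = res$overall, gene = f$gene, moi = f$moi,
                 call = f$call, n_lp = nrow(f$lp_variants),
                 n_vus = nrow(f$vus_variants), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
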