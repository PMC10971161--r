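# Shared builders for toy transcripts, variant tables and knowledge bases,
# plus independent rule-transcription oracles used to cross-check the
# pipelined implementations.

# Three-exon plus-strand toy transcript with UTRs at both ends.
# Exons 1001-1200, 2001-2200, 3001-3200; CDS 1051-3150.
toy_tx3 <- function(strand = "+") {
  transcript_model("TX_TOY3.1", "TOY3", strand,
                   exon_starts = c(1001L, 2001L, 3001L),
                   exon_ends = c(1200L, 2200L, 3200L),
                   cds_start = 1051L, cds_end = 3150L)
}

# Two-exon transcript for splice-site tests: exons 501-700 and 1501-1700,
# CDS 531-1670.
toy_tx2 <- function() {
  transcript_model("TX_TOY2.1", "TOY2", "+",
                   exon_starts = c(501L, 1501L),
                   exon_ends = c(700L, 1700L),
                   cds_start = 531L, cds_end = 1670L)
}

# Quick variant-table builder with sensible defaults.
mk_variants <- function(pos, sample_id = "S1", chrom = "1", gene = "G1",
                        ref = "A", alt = "T", var_type = "SNV",
                        population_af = 1e-4, vaf = 0.5, zygosity = "het",
                        ...) {
  n <- length(pos)
  cols <- lapply(c(list(sample_id = sample_id, chrom = chrom, pos = pos,
                        gene = gene, ref = ref, alt = alt,
                        var_type = var_type, population_af = population_af,
                        vaf = vaf, zygosity = zygosity), list(...)),
                 rep_len, n)
  variant_table(as.data.frame(cols, stringsAsFactors = FALSE))
}

# Quick knowledge base: one row per entry given as list(chrom, pos, ref, alt,
# source, classification).
mk_kb <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(knowledge_base(data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     source = character(),
                                     classification = character(),
                                     stringsAsFactors = FALSE)))
  knowledge_base(do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], pos = as.integer(r[[2]]), ref = r[[3]],
               alt = r[[4]], source = r[[5]], classification = r[[6]],
               stringsAsFactors = FALSE))))
}

# Quick one-gene candidate table for MOI tests.
mk_cands <- function(working_class, zygosity, gene = "G1", vaf = NULL,
                     var_type = "SNV", in_cis = FALSE, sample_id = "S1") {
  n <- length(working_class)
  if (is.null(vaf))
    vaf <- ifelse(rep_len(zygosity, n) %in% c("hom", "hemi"), 0.99, 0.5)
  v <- mk_variants(pos = seq_len(n) * 10L + 1000L, sample_id = sample_id,
                   gene = gene, vaf = vaf, zygosity = zygosity,
                   var_type = var_type, in_cis = in_cis)
  v$selection_reason <- rep("db_lp", n)
  v$working_class <- rep_len(working_class, n)
  v$reviewed <- rep(FALSE, n)
  v
}

# Independent transcription of the mode-of-inheritance call rules, written
# directly from the rule statement (counts only; small variants, no phase).
oracle_moi_call <- function(moi, classes, zygosities, strategy) {
  lp <- classes %in% c("P", "LP")
  vus <- classes == "VUS"
  alleles <- sum(ifelse(zygosities[lp] == "hom", 2L,
                        ifelse(zygosities[lp] == "hemi", 2L,
                               ifelse(zygosities[lp] == "het", 1L, 0L))))
  n_lp <- sum(lp)
  one_het_lp <- n_lp == 1L && sum(lp & zygosities == "het") == 1L
  any_het_vus <- any(vus & zygosities == "het")
  if (moi == "AD") {
    if (n_lp >= 1L) return("positive")
    return("negative")
  }
  if (moi == "XLR" &&
      any(lp & zygosities %in% c("hom", "hemi"))) return("positive")
  if (alleles >= 2L) return("positive")
  if (one_het_lp) {
    if (strategy == "extended" && any_het_vus) return("positive")
    return("carrier")
  }
  "negative"
}

# Independent per-branch predicate checker for the strict filter: tests each
# variant against the three retention branches one at a time using the
# scalar lookup/classification entry points.
oracle_strict_keep <- function(variants, kb, transcripts, config) {
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$raw_only) return(FALSE)
    if (v$population_af >= config$af_cutoff) return(FALSE)
    verdict <- lookup_classification(v, kb)$verdict
    tx <- if (is.null(transcripts)) NULL else
      nbscreen:::transcript_for(transcripts, v$transcript_id, v$gene)
    cons <- if (is.null(tx)) NA_character_ else
      classify_consequence(v, tx, config$nmd_rule_nt, config$splice_window)
    branch_a <- verdict == "LP_or_P"
    branch_b <- !is.na(cons) &&
      cons %in% c("truncating_nmd", "canonical_splice") && verdict == "none"
    branch_c <- !is.na(cons) && cons == "splice_region_pm3"
    branch_a || branch_b || branch_c
  }, logical(1))
}
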