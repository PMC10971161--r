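# Domain types for variants, transcripts and gene panels, plus consequence
# classification (truncation vs NMD escape, splice window, UTRs) and the
# heterozygous VAF window. Coordinates are 1-based fully closed, GRCh37-style.

VAR_TYPES <- c("SNV", "indel", "delins", "CNV_del", "CNV_dup")
ZYGOSITIES <- c("het", "hom", "hemi", "unknown")
MOI_VALUES <- c("AD", "AR", "XLR")

#' Consequence classes recognised by the pipeline
#'
#' @return Character vector of the closed consequence vocabulary.
#' @export
consequence_classes <- function() {
  c("truncating_nmd", "truncating_nmd_escape", "canonical_splice",
    "splice_region_pm3", "missense", "synonymous", "utr5", "utr3",
    "deep_intronic", "other")
}

#' Genomic interval
#'
#' 1-based, fully closed interval on a named chromosome.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param assembly Genome build label; fixtures use `"GRCh37"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end = start, assembly = "GRCh37") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval: need start <= end", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end, assembly = assembly),
            class = "genomic_interval")
}

#' Transcript model
#'
#' A minimal transcript: ordered exons, CDS bounds and strand. Exons are given
#' in genomic order (ascending coordinates); the strand determines 5' to 3'
#' direction. CDS bounds are genomic positions of the translation start/stop
#' and must fall inside exons.
#'
#' @param transcript_id Accession (with version) identifying the transcript.
#' @param gene Gene symbol.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon bounds, ascending,
#'   non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding sequence
#'   (`cds_start <= cds_end` in genomic coordinates regardless of strand).
#' @param is_mane Whether this is the MANE/canonical transcript for the gene.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, strand, exon_starts,
                             exon_ends, cds_start, cds_end, is_mane = TRUE) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L)
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (any(exon_starts > exon_ends))
    stop("exon start > end", call. = FALSE)
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop("exons must be ordered and non-overlapping", call. = FALSE)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start > cds_end) stop("cds_start must be <= cds_end", call. = FALSE)
  in_exon <- function(p) any(exon_starts <= p & p <= exon_ends)
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("CDS bounds must fall within exons", call. = FALSE)
  structure(list(transcript_id = transcript_id, gene = gene, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = cds_start, cds_end = cds_end,
                 is_mane = isTRUE(is_mane)),
            class = "transcript_model")
}

#' Build a transcript set keyed by transcript id
#'
#' @param ... `transcript_model` objects (or a single list of them).
#' @return Named list of transcripts with a `gene_index` attribute mapping
#'   gene symbols to the MANE (or first) transcript id.
#' @export
transcript_set <- function(...) {
  txs <- list(...)
  if (length(txs) == 1L && !inherits(txs[[1]], "transcript_model"))
    txs <- txs[[1]]
  ok <- vapply(txs, inherits, logical(1), "transcript_model")
  if (!all(ok)) stop("all elements must be transcript_model objects", call. = FALSE)
  names(txs) <- vapply(txs, `[[`, character(1), "transcript_id")
  genes <- vapply(txs, `[[`, character(1), "gene")
  mane <- vapply(txs, `[[`, logical(1), "is_mane")
  # prefer the MANE transcript per gene, else the first listed
  ord <- order(genes, !mane)
  idx <- names(txs)[ord][!duplicated(genes[ord])]
  names(idx) <- genes[ord][!duplicated(genes[ord])]
  attr(txs, "gene_index") <- idx
  txs
}

transcript_for <- function(transcripts, transcript_id = NA, gene = NA) {
  if (!is.na(transcript_id) && transcript_id %in% names(transcripts))
    return(transcripts[[transcript_id]])
  idx <- attr(transcripts, "gene_index")
  if (!is.na(gene) && gene %in% names(idx)) return(transcripts[[idx[[gene]]]])
  NULL
}

variant_columns <- function() {
  c("sample_id", "chrom", "pos", "end", "ref", "alt", "gene", "transcript_id",
    "hgvs_c", "hgvs_p", "var_type", "csq", "population_af", "vaf", "zygosity",
    "coverage_ok", "raw_only", "in_cis")
}

#' Canonical variant table
#'
#' Normalises a data frame of observed variants (one row per variant per
#' sample) to the canonical column set and validates ranges and vocabularies.
#' Missing optional columns are filled with defaults: `end = pos` for small
#' variants, `coverage_ok = TRUE`, `raw_only = FALSE`, `in_cis = FALSE`.
#'
#' @param df Data frame with at least `sample_id`, `chrom`, `pos`, `gene`,
#'   `var_type`, `population_af`, `vaf`, `zygosity`.
#' @return Validated data frame with columns [variant_columns()] plus
#'   `variant_key`.
#' @export
variant_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "gene", "var_type",
            "population_af", "vaf", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  defaults <- list(end = NA_integer_, ref = NA_character_, alt = NA_character_,
                   transcript_id = NA_character_, hgvs_c = NA_character_,
                   hgvs_p = NA_character_, csq = NA_character_,
                   coverage_ok = TRUE, raw_only = FALSE, in_cis = FALSE)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  df$pos <- as.integer(df$pos)
  df$end <- ifelse(is.na(df$end), df$pos, as.integer(df$end))
  if (nrow(df)) {
    if (any(!df$var_type %in% VAR_TYPES))
      stop("unknown var_type token", call. = FALSE)
    if (any(!df$zygosity %in% ZYGOSITIES))
      stop("unknown zygosity token", call. = FALSE)
    bad_af <- !is.na(df$population_af) &
      (df$population_af < 0 | df$population_af > 1)
    bad_vaf <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
    if (any(bad_af)) stop("population_af outside [0, 1]", call. = FALSE)
    if (any(bad_vaf)) stop("vaf outside [0, 1]", call. = FALSE)
    cnv <- df$var_type %in% c("CNV_del", "CNV_dup")
    if (any(cnv & (df$end < df$pos)))
      stop("CNV records must span >= 1 bp", call. = FALSE)
    if (any(cnv & df$zygosity == "unknown"))
      stop("CNV records must carry het/hemi/hom zygosity", call. = FALSE)
  }
  df$variant_key <- variant_key(df$chrom, df$pos, df$ref, df$alt, df$var_type,
                                df$end)
  df[, c(variant_columns(), "variant_key")]
}

#' Single variant record
#'
#' Convenience wrapper building a one-row [variant_table()].
#'
#' @param sample_id,chrom,pos,gene,var_type,population_af,vaf,zygosity Required
#'   fields; see [variant_table()].
#' @param ... Optional fields (`ref`, `alt`, `end`, `csq`, `hgvs_c`, ...).
#' @return One-row validated variant data frame.
#' @export
variant_record <- function(sample_id, chrom, pos, gene, var_type = "SNV",
                           population_af = 0, vaf = 0.5, zygosity = "het",
                           ...) {
  extra <- list(...)
  base <- list(sample_id = sample_id, chrom = chrom, pos = pos, gene = gene,
               var_type = var_type, population_af = population_af, vaf = vaf,
               zygosity = zygosity)
  variant_table(as.data.frame(c(base, extra), stringsAsFactors = FALSE))
}

#' Gene panel table
#'
#' @param df Data frame with columns `gene`, `moi`, `disorder`, `chrom`
#'   (optional columns are kept). X-linked recessive entries must sit on
#'   chromosome X.
#' @return Validated panel data frame.
#' @export
panel_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("gene", "moi", "chrom")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"disorder" %in% names(df)) df$disorder <- rep(NA_character_, nrow(df))
  if (!"mild_phenotype" %in% names(df))
    df$mild_phenotype <- rep(FALSE, nrow(df))
  if (any(!df$moi %in% MOI_VALUES)) stop("unknown MOI token", call. = FALSE)
  if (any(df$moi == "XLR" & df$chrom != "X"))
    stop("XLR genes must be on chromosome X", call. = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate panel gene", call. = FALSE)
  df
}

csq_token_map <- function(csq) {
  csq <- tolower(csq)
  if (csq %in% c("stop_gained", "nonsense")) return("ptc")
  if (csq %in% c("frameshift", "frameshift_variant")) return("ptc")
  if (csq %in% c("start_lost", "startloss", "stop_lost", "stoploss",
                 "start_loss", "stop_loss")) return("truncating_fixed")
  if (csq %in% c("missense", "missense_variant")) return("missense")
  if (csq %in% c("synonymous", "synonymous_variant")) return("synonymous")
  "other"
}

# Coding-sequence position of a genomic position, walking exons 5'->3'.
coding_offsets <- function(tx) {
  lo <- pmax(tx$exon_starts, tx$cds_start)
  hi <- pmin(tx$exon_ends, tx$cds_end)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  if (tx$strand == "-") { tmp <- lo; lo <- rev(lo); hi <- rev(hi) }
  list(lo = lo, hi = hi, len = hi - lo + 1L)
}

coding_position <- function(tx, pos) {
  co <- coding_offsets(tx)
  for (i in seq_along(co$lo)) {
    a <- co$lo[i]; b <- co$hi[i]
    if (pos >= a && pos <= b) {
      within <- if (tx$strand == "+") pos - a else b - pos
      before <- if (i > 1L) sum(co$len[seq_len(i - 1L)]) else 0L
      return(list(cds_pos = before + within + 1L, exon_index = i,
                  n_coding_exons = length(co$lo)))
    }
  }
  NULL
}

# TRUE if a premature termination codon at this genomic position escapes
# nonsense-mediated decay under the 50-nt rule: last coding exon, or within
# the final nmd_rule_nt coding nucleotides of the penultimate coding exon.
nmd_escapes <- function(tx, pos, nmd_rule_nt = 50L) {
  cp <- coding_position(tx, pos)
  if (is.null(cp)) return(FALSE)
  if (cp$n_coding_exons == 1L) return(TRUE)
  co <- coding_offsets(tx)
  junction_cds <- sum(co$len[seq_len(cp$n_coding_exons - 1L)])
  cp$cds_pos > junction_cds - nmd_rule_nt
}

#' Classify the transcript-level consequence of a variant
#'
#' Assigns the single most severe applicable class for a (variant, transcript)
#' pair. Intronic positions within 1-2 bp of an exon boundary are canonical
#' splice sites; exactly 3 bp away is the extended splice region; further is
#' deep intronic. Exonic positions outside the CDS are UTRs. Within the CDS
#' the provided consequence annotation (`csq`) is used; premature termination
#' codons (stop-gain, frameshift) are split into `truncating_nmd` versus
#' `truncating_nmd_escape` by the 50-nt nonsense-mediated-decay rule.
#' Start-loss and stop-loss are always `truncating_nmd`.
#'
#' @param variant One-row variant data frame (or list) with `pos` and
#'   optionally `csq`.
#' @param transcript A [transcript_model()].
#' @param nmd_rule_nt NMD boundary rule, in coding nucleotides upstream of the
#'   last exon-exon junction (default 50).
#' @param splice_window Intronic splice window in bp (default 3).
#' @return A single consequence class string; see [consequence_classes()].
#' @export
classify_consequence <- function(variant, transcript, nmd_rule_nt = 50L,
                                 splice_window = 3L) {
  tx <- transcript
  if (!inherits(tx, "transcript_model"))
    stop("transcript must be a transcript_model", call. = FALSE)
  pos <- as.integer(variant$pos)
  if (is.na(pos)) stop("variant position missing", call. = FALSE)
  span_lo <- min(tx$exon_starts) - splice_window
  span_hi <- max(tx$exon_ends) + splice_window
  if (pos < span_lo || pos > span_hi)
    stop("variant does not overlap the transcript span", call. = FALSE)
  exon_idx <- which(tx$exon_starts <= pos & pos <= tx$exon_ends)
  if (!length(exon_idx)) {
    # intronic (or padded flank): offset to nearest exon boundary
    d_up <- tx$exon_starts - pos
    d_dn <- pos - tx$exon_ends
    d <- min(c(d_up[d_up > 0], d_dn[d_dn > 0]))
    if (d <= 2L) return("canonical_splice")
    if (d <= splice_window) return("splice_region_pm3")
    return("deep_intronic")
  }
  if (pos < tx$cds_start || pos > tx$cds_end) {
    upstream <- pos < tx$cds_start
    if (tx$strand == "-") upstream <- !upstream
    return(if (upstream) "utr5" else "utr3")
  }
  csq <- variant$csq
  if (is.null(csq) || length(csq) != 1L || is.na(csq)) return("other")
  kind <- csq_token_map(csq)
  switch(kind,
         ptc = if (nmd_escapes(tx, pos, nmd_rule_nt)) "truncating_nmd_escape"
               else "truncating_nmd",
         truncating_fixed = "truncating_nmd",
         kind)
}

#' Annotate a variant table with consequence classes
#'
#' Vectorised wrapper around [classify_consequence()]. Transcripts are matched
#' by `transcript_id`, falling back to the gene's MANE transcript. CNV records
#' get class `NA`. Small variants with no matching transcript fall back to a
#' direct mapping of their `csq` token (intronic/UTR tokens included), so
#' pre-annotated input does not require toy transcript models.
#'
#' @param variants Variant data frame ([variant_table()]).
#' @param transcripts [transcript_set()] or `NULL`.
#' @param nmd_rule_nt,splice_window See [classify_consequence()].
#' @return `variants` with a `consequence` column added.
#' @export
annotate_consequences <- function(variants, transcripts = NULL,
                                  nmd_rule_nt = 50L, splice_window = 3L) {
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  token_fallback <- function(csq) {
    if (is.na(csq)) return("other")
    tok <- tolower(csq)
    if (tok %in% consequence_classes()) return(tok)
    if (tok %in% c("splice_acceptor", "splice_donor", "splice_acceptor_variant",
                   "splice_donor_variant", "canonical_splice_site"))
      return("canonical_splice")
    if (tok %in% c("splice_region", "splice_region_variant"))
      return("splice_region_pm3")
    if (tok %in% c("5_prime_utr_variant", "utr_5")) return("utr5")
    if (tok %in% c("3_prime_utr_variant", "utr_3")) return("utr3")
    if (tok %in% c("intron_variant", "intronic")) return("deep_intronic")
    kind <- csq_token_map(tok)
    # no transcript: assume a PTC is NMD-subject
    switch(kind, ptc = "truncating_nmd", truncating_fixed = "truncating_nmd",
           kind)
  }
  for (i in seq_len(n)) {
    if (variants$var_type[i] %in% c("CNV_del", "CNV_dup")) next
    tx <- if (is.null(transcripts)) NULL else
      transcript_for(transcripts, variants$transcript_id[i], variants$gene[i])
    out[i] <- if (is.null(tx)) token_fallback(variants$csq[i]) else
      classify_consequence(variants[i, ], tx, nmd_rule_nt, splice_window)
  }
  variants$consequence <- out
  variants
}

#' Heterozygous VAF window test
#'
#' TRUE iff the variant allele fraction lies in the (inclusive) heterozygous
#' window, 40-60% by default.
#'
#' @param vaf Numeric vector of variant allele fractions in `[0, 1]`.
#' @param window Length-2 numeric, default `c(0.40, 0.60)`.
#' @return Logical vector.
#' @export
vaf_in_het_window <- function(vaf, window = c(0.40, 0.60)) {
  if (any(!is.na(vaf) & (vaf < 0 | vaf > 1)))
    stop("vaf outside [0, 1]", call. = FALSE)
  !is.na(vaf) & vaf >= window[1] & vaf <= window[2]
}

#' Infer zygosity from VAF
#'
#' Used only when upstream genotype calls are absent (synthetic data): het if
#' the VAF falls in the heterozygous window, hom if `vaf >= hom_threshold`,
#' otherwise unknown. Unknown is never auto-promoted downstream.
#'
#' @param vaf Numeric vector in `[0, 1]`.
#' @param window Heterozygous VAF window.
#' @param hom_threshold Minimum VAF for a homozygous call (default 0.85).
#' @return Character vector of zygosity tokens.
#' @export
infer_zygosity <- function(vaf, window = c(0.40, 0.60), hom_threshold = 0.85) {
  out <- rep("unknown", length(vaf))
  out[vaf_in_het_window(vaf, window)] <- "het"
  out[!is.na(vaf) & vaf >= hom_threshold] <- "hom"
  out
}

#' Merge adjacent small-variant calls into delins records
#'
#' Deletion-insertions located in cis are sometimes emitted by callers as
#' separate adjacent events. Runs of SNV/indel records (one sample, one gene,
#' sorted by position) in which consecutive calls lie within `max_gap` bp and
#' differ in VAF by at most `vaf_tol` are merged into a single delins record
#' whose VAF is the mean of the merged VAFs. Existing delins and CNV records
#' pass through unchanged, which makes the operation idempotent.
#'
#' @param variants Variant data frame for one sample and one gene, sorted by
#'   position.
#' @param max_gap Maximum gap in bp between consecutive mergeable calls
#'   (default 10).
#' @param vaf_tol Maximum pairwise VAF difference within a run (default 0.1).
#' @return Variant data frame with merged records; row count <= input.
#' @export
merge_adjacent_calls <- function(variants, max_gap = 10L, vaf_tol = 0.1) {
  if (nrow(variants) <= 1L) return(variants)
  if (length(unique(variants$sample_id)) > 1L ||
      length(unique(variants$gene)) > 1L)
    stop("merge_adjacent_calls expects one sample and one gene", call. = FALSE)
  if (is.unsorted(variants$pos))
    stop("variants must be sorted by position", call. = FALSE)
  n <- nrow(variants)
  mergeable <- variants$var_type %in% c("SNV", "indel")
  run <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    extend <- FALSE
    if (mergeable[i] && i > 1L && mergeable[i - 1L] && run[i - 1L] == cur) {
      gap_ok <- variants$pos[i] - variants$end[i - 1L] <= max_gap
      vafs <- variants$vaf[seq_len(i - 1L)][run[seq_len(i - 1L)] == cur]
      vaf_ok <- all(abs(variants$vaf[i] - vafs) <= vaf_tol)
      extend <- gap_ok && vaf_ok
    }
    if (!extend) cur <- cur + 1L
    run[i] <- cur
  }
  pieces <- split(seq_len(n), run)
  out <- lapply(pieces, function(idx) {
    if (length(idx) == 1L) return(variants[idx, ])
    v <- variants[idx, ]
    merged <- v[1L, ]
    merged$end <- max(v$end)
    merged$var_type <- "delins"
    merged$ref <- paste0(v$ref, collapse = "")
    merged$alt <- paste0(v$alt, collapse = "")
    merged$vaf <- mean(v$vaf)
    merged$hgvs_c <- NA_character_
    merged$hgvs_p <- NA_character_
    merged$variant_key <- variant_key(merged$chrom, merged$pos, merged$ref,
                                      merged$alt, merged$var_type, merged$end)
    merged
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
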