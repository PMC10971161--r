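# Variant knowledge base: per-source classifications (HGMD / ClinVar / VKGL /
# local) aggregated into the single verdict the strict filter consumes.

KB_SOURCES <- c("HGMD", "ClinVar", "VKGL", "local")
KB_CLASSES <- c("P", "LP", "VUS", "LB", "B", "DM", "conflicting")
KB_VERDICTS <- c("LP_or_P", "VUS", "benign_or_likely_benign", "none",
                 "conflicting")

#' Normalised variant key
#'
#' Builds the `chrom:pos:REF:ALT` key used to join observed variants against
#' knowledge-base entries and review tables. Alleles are uppercased and a
#' shared suffix then shared prefix is trimmed (minimal representation, with
#' the position advanced over the trimmed prefix). CNV records are keyed by
#' their span and type instead of alleles.
#'
#' @param chrom,pos,ref,alt Vectors describing the variant.
#' @param var_type Variant type vector (defaults to small-variant handling).
#' @param end End positions, used for CNV keys.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt, var_type = NULL, end = NULL) {
  n <- length(chrom)
  pos <- as.integer(pos)
  ref <- toupper(ifelse(is.na(ref), "", ref))
  alt <- toupper(ifelse(is.na(alt), "", alt))
  out <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(var_type) && var_type[i] %in% c("CNV_del", "CNV_dup")) {
      e <- if (is.null(end)) pos[i] else end[i]
      out[i] <- paste(chrom[i], pos[i], e, var_type[i], sep = ":")
      next
    }
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim common suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix, advancing the position
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    out[i] <- paste(chrom[i], p, r, a, sep = ":")
  }
  out
}

#' Construct/validate a knowledge-base table
#'
#' One row per (variant, source). `DM` (disease-causing mutation) is only
#' valid for source HGMD. Duplicate (variant_key, source) rows are an error.
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`, `source`,
#'   `classification` and optional `release`.
#' @return Validated data frame with a `variant_key` column, class `kb_table`.
#' @export
knowledge_base <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "source", "classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("knowledge base missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"release" %in% names(df)) df$release <- rep(NA_character_, nrow(df))
  bad_src <- !df$source %in% KB_SOURCES
  if (any(bad_src))
    stop("unknown knowledge-base source in row(s) ",
         paste(which(bad_src), collapse = ", "), call. = FALSE)
  bad_cls <- !df$classification %in% KB_CLASSES
  if (any(bad_cls))
    stop("unknown classification token in row(s) ",
         paste(which(bad_cls), collapse = ", "), call. = FALSE)
  if (any(df$classification == "DM" & df$source != "HGMD"))
    stop("classification DM is only valid for source HGMD", call. = FALSE)
  df$variant_key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df[, c("variant_key", "source")]))
    stop("duplicate (variant, source) entry in knowledge base", call. = FALSE)
  class(df) <- c("kb_table", "data.frame")
  df
}

#' Load a knowledge base from TSV
#'
#' @param path TSV file with header
#'   `chrom pos ref alt source classification release`.
#' @return A validated [knowledge_base()] table.
#' @export
load_knowledgebase <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$pos <- as.integer(df$pos)
  knowledge_base(df)
}

# Per-key aggregation used by the vectorised lookup.
kb_aggregate <- function(kb) {
  if (!nrow(kb))
    return(data.frame(variant_key = character(), verdict = character(),
                      sources = character(), best_class = character(),
                      stringsAsFactors = FALSE))
  path_side <- kb$classification %in% c("P", "LP", "DM")
  benign_side <- kb$classification %in% c("B", "LB")
  vus_side <- kb$classification %in% c("VUS", "conflicting")
  keys <- unique(kb$variant_key)
  verdict <- character(length(keys))
  sources <- character(length(keys))
  best <- character(length(keys))
  for (i in seq_along(keys)) {
    sel <- kb$variant_key == keys[i]
    has_p <- any(path_side & sel)
    has_b <- any(benign_side & sel)
    has_v <- any(vus_side & sel)
    verdict[i] <- if (has_p && has_b) "conflicting"
      else if (has_p) "LP_or_P"
      else if (has_v) "VUS"
      else "benign_or_likely_benign"
    support <- if (has_p && !has_b) sel & path_side else sel
    sources[i] <- paste(unique(kb$source[support]), collapse = ",")
    best[i] <- if (any(sel & kb$classification %in% c("P", "DM"))) "P"
      else if (any(sel & kb$classification == "LP")) "LP"
      else if (has_v) "VUS"
      else "B"
  }
  data.frame(variant_key = keys, verdict = verdict, sources = sources,
             best_class = best, stringsAsFactors = FALSE)
}

#' Aggregated classification of one variant across knowledge-base sources
#'
#' A variant is "conclusively described" as (likely) pathogenic when at least
#' one source reports P, LP or DM and no source reports B/LB; pathogenic and
#' benign entries together yield `conflicting`; otherwise the best available
#' class (VUS before benign) decides; absence from all sources is `none`.
#' Entry order never matters.
#'
#' @param variant One-row variant data frame (or anything with
#'   `chrom`/`pos`/`ref`/`alt`, or a precomputed `variant_key`).
#' @param kb A [knowledge_base()] table.
#' @return List with `verdict` and `supporting_sources`.
#' @export
lookup_classification <- function(variant, kb) {
  key <- if (!is.null(variant$variant_key)) variant$variant_key
         else variant_key(variant$chrom, variant$pos, variant$ref, variant$alt)
  agg <- kb_aggregate(kb)
  i <- match(key, agg$variant_key)
  if (is.na(i))
    return(list(verdict = "none", supporting_sources = character()))
  list(verdict = agg$verdict[i],
       supporting_sources = strsplit(agg$sources[i], ",", fixed = TRUE)[[1]])
}

# Vectorised verdict + best pathogenic class for a variant table.
kb_verdicts <- function(variants, kb) {
  agg <- kb_aggregate(kb)
  i <- match(variants$variant_key, agg$variant_key)
  verdict <- ifelse(is.na(i), "none", agg$verdict[i])
  best <- ifelse(is.na(i), NA_character_, agg$best_class[i])
  data.frame(verdict = verdict, best_class = best, stringsAsFactors = FALSE)
}
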