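# Pipeline configuration, annotated-VCF input/output, report writers and the
# command-line entry point.

#' Pipeline configuration
#'
#' All thresholds consumed by the filters flow from this object: the
#' population allele-frequency cutoff (strict `<`, default 1%), the
#' heterozygous VAF window (inclusive 40-60%), the NMD boundary rule (50
#' coding nt), the intronic splice window (+/-3), the VUS-extension trigger
#' mode, and the defaults for adjacent-call merging and the depth guard used
#' when deriving VAF/zygosity from allele depths.
#'
#' @param af_cutoff Population allele-frequency cutoff, `0 < af_cutoff < 1`.
#' @param vaf_window Heterozygous VAF window `c(low, high)`, `low < high`.
#' @param nmd_rule_nt NMD boundary in coding nucleotides.
#' @param splice_window Intronic splice window in bp.
#' @param vus_trigger_mode `"exactly_one"` or `"at_least_one"` (likely)
#'   pathogenic heterozygote required to trigger the VUS extension.
#' @param strategy Default screening strategy, `"strict"` or `"extended"`.
#' @param seed Integer seed for any stochastic step.
#' @param merge_max_gap,merge_vaf_tol Defaults for [merge_adjacent_calls()].
#' @param min_depth Depth below which AD-derived zygosity is `unknown`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(af_cutoff = 0.01, vaf_window = c(0.40, 0.60),
                            nmd_rule_nt = 50L, splice_window = 3L,
                            vus_trigger_mode = c("exactly_one",
                                                 "at_least_one"),
                            strategy = c("strict", "extended"), seed = 1L,
                            merge_max_gap = 10L, merge_vaf_tol = 0.1,
                            min_depth = 10L) {
  vus_trigger_mode <- match.arg(vus_trigger_mode)
  strategy <- match.arg(strategy)
  stopifnot(af_cutoff > 0, af_cutoff < 1,
            length(vaf_window) == 2L, vaf_window[1] < vaf_window[2])
  structure(list(af_cutoff = af_cutoff, vaf_window = vaf_window,
                 nmd_rule_nt = as.integer(nmd_rule_nt),
                 splice_window = as.integer(splice_window),
                 vus_trigger_mode = vus_trigger_mode, strategy = strategy,
                 seed = as.integer(seed),
                 merge_max_gap = as.integer(merge_max_gap),
                 merge_vaf_tol = merge_vaf_tol,
                 min_depth = as.integer(min_depth),
                 format_version = 1L),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return [pipeline_config()].
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  lst$format_version <- NULL
  do.call(pipeline_config, lst)
}

#' Write a pipeline configuration to YAML
#' @param config [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an annotated VCF into a variant table
#'
#' Expects INFO keys `GENE`, `TRANSCRIPT`, `CSQ` (consequence token) and `AF`
#' (population allele frequency), plus per-sample FORMAT `GT` and `VAF` (or
#' `AD`, from which VAF is derived as alt/(ref+alt); depth below `min_depth`
#' yields zygosity `unknown`). Optional INFO keys `END` and `VARTYPE` carry
#' CNV records. Multi-allelic sites are decomposed into one record per
#' sample-allele; reference-homozygous and no-call genotypes are dropped.
#'
#' @param path VCF file (plain or bgzipped).
#' @param config [pipeline_config()] (for `min_depth`).
#' @return A [variant_table()] with one row per sample-allele.
#' @export
read_annotated_vcf <- function(path, config = pipeline_config()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0L)
    stop("no records in VCF", call. = FALSE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  gene <- info_get("GENE"); txid <- info_get("TRANSCRIPT")
  csq <- info_get("CSQ"); af <- suppressWarnings(as.numeric(info_get("AF")))
  if (all(is.na(gene)))
    stop("VCF is missing the GENE INFO key", call. = FALSE)
  vend <- suppressWarnings(as.integer(info_get("END")))
  vtype <- info_get("VARTYPE")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  has_vaf <- "VAF" %in% unlist(strsplit(unique(vcf@gt[, "FORMAT"]), ":"))
  vaf_m <- if (has_vaf)
    suppressWarnings(vcfR::extract.gt(vcf, element = "VAF",
                                      as.numeric = TRUE)) else NULL
  ad_m <- if (!has_vaf) vcfR::extract.gt(vcf, element = "AD") else NULL
  samples <- colnames(gt)
  rows <- list()
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      for (s in samples) {
        g <- gt[r, s]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) next
        alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
        n_alt <- sum(alleles == as.character(a))
        if (n_alt == 0L) next
        zyg <- if (length(alleles) == 1L) "hemi"
               else if (n_alt == 2L) "hom" else "het"
        vaf <- NA_real_
        if (!is.null(vaf_m)) vaf <- vaf_m[r, s]
        else if (!is.null(ad_m) && !is.na(ad_m[r, s])) {
          ad <- suppressWarnings(as.numeric(
            strsplit(ad_m[r, s], ",", fixed = TRUE)[[1]]))
          depth <- sum(ad, na.rm = TRUE)
          vaf <- if (depth > 0) ad[a + 1L] / depth else NA_real_
          if (is.na(depth) || depth < config$min_depth) zyg <- "unknown"
        }
        vt <- if (!is.na(vtype[r]) && nzchar(vtype[r])) vtype[r]
              else if (alts[a] %in% c("<DEL>")) "CNV_del"
              else if (alts[a] %in% c("<DUP>")) "CNV_dup"
              else if (nchar(fix$REF[r]) == 1L && nchar(alts[a]) == 1L) "SNV"
              else "indel"
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, chrom = fix$CHROM[r],
          pos = as.integer(fix$POS[r]),
          end = if (!is.na(vend[r])) vend[r] else NA_integer_,
          ref = if (vt %in% c("CNV_del", "CNV_dup")) NA_character_
                else fix$REF[r],
          alt = if (vt %in% c("CNV_del", "CNV_dup")) NA_character_
                else alts[a],
          gene = gene[r], transcript_id = txid[r], csq = csq[r],
          population_af = af[r], vaf = vaf, zygosity = zyg,
          var_type = vt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no sample-alleles in VCF", call. = FALSE)
  variant_table(do.call(rbind, rows))
}

#' Write a variant table as an annotated VCF
#'
#' Emits a VCF 4.2 file with the INFO/FORMAT layout [read_annotated_vcf()]
#' consumes; all fields the pipeline uses round-trip. Records are grouped by
#' locus; samples without the allele get `./.`.
#'
#' @param variants A [variant_table()].
#' @param path Output path (plain text).
#' @param sample_ids Column order of samples; defaults to order seen.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Transcript accession\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence token\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=VARTYPE,Number=1,Type=String,Description=\"Variant type\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  is_cnv <- variants$var_type %in% c("CNV_del", "CNV_dup")
  ref <- ifelse(is_cnv, "N", variants$ref)
  alt <- ifelse(variants$var_type == "CNV_del", "<DEL>",
                ifelse(variants$var_type == "CNV_dup", "<DUP>",
                       variants$alt))
  locus <- paste(variants$chrom, variants$pos, ref, alt, sep = "\t")
  ord <- order(variants$chrom, variants$pos, alt)
  lines <- character()
  for (lo in unique(locus[ord])) {
    idx <- which(locus == lo)
    v1 <- variants[idx[1L], ]
    info <- paste0("GENE=", v1$gene,
                   ";TRANSCRIPT=", ifelse(is.na(v1$transcript_id), ".",
                                          v1$transcript_id),
                   ";CSQ=", ifelse(is.na(v1$csq), ".", v1$csq),
                   ";AF=", format(v1$population_af, scientific = FALSE,
                                  trim = TRUE),
                   ";END=", v1$end,
                   ";VARTYPE=", v1$var_type)
    cells <- vapply(sample_ids, function(s) {
      j <- idx[variants$sample_id[idx] == s]
      if (!length(j)) return("./.:.")
      z <- variants$zygosity[j[1L]]
      g <- switch(z, het = "0/1", hom = "1/1", hemi = "1", "./.")
      paste0(g, ":", format(variants$vaf[j[1L]], trim = TRUE))
    }, character(1))
    lines <- c(lines, paste(c(strsplit(lo, "\t", fixed = TRUE)[[1L]][1:2],
                              ".", strsplit(lo, "\t",
                                            fixed = TRUE)[[1L]][3:4],
                              ".", "PASS", info, "GT:VAF", cells),
                            collapse = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write screen results and confusion counts as JSON and TSV reports
#'
#' Reruns with the same inputs produce byte-identical files (no timestamps).
#' Carrierships are omitted unless `include_incidental` is set, since
#' carrier findings are outside the scope of newborn screening reporting.
#'
#' @param results Screen results ([screen_cohort()]), or `NULL`.
#' @param counts `confusion_counts`, or `NULL`.
#' @param path Output path stem; writes `<path>.json` and `<path>.tsv`.
#' @param include_incidental Include carrierships in the report.
#' @param carrierships Carriership table ([detect_carriership()]).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results = NULL, counts = NULL, path,
                         include_incidental = FALSE, carrierships = NULL) {
  out <- list(format_version = 1L)
  if (!is.null(results)) {
    tab <- screen_results_table(results)
    out$samples <- tab
  }
  if (!is.null(counts))
    out$counts <- list(tp = counts$tp, fp = counts$fp, fn = counts$fn,
                       tn = counts$tn, n_evaluable = counts$n_evaluable)
  if (include_incidental && !is.null(carrierships))
    out$carrierships <- carrierships
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(results)) {
    utils::write.table(screen_results_table(results), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (!is.null(counts)) {
    utils::write.table(as.data.frame(out$counts), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(json_path, tsv_path))
}

cli_usage <- function() {
  paste(
    "usage: nbscreen <subcommand> [options]",
    "subcommands:",
    "  replay   --method tNGS|WES|WGS --strategy strict|extended",
    "           [--fixture FILE] [--out STEM]",
    "  simulate --n N --seed S --out-dir DIR [--n-genes G]",
    "  screen   --vcf FILE --panel FILE --kb FILE [--review FILE]",
    "           [--config FILE] [--strategy strict|extended] [--out STEM]",
    "  funnel   --vcf FILE --panel FILE --kb FILE [--review FILE]",
    "           [--config FILE] [--out STEM]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (!length(args)) return(NULL)
  sub <- args[1L]
  args <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) return(NULL)
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) return(NULL)
    opts[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  list(sub = sub, opts = opts)
}

#' Command-line entry point
#'
#' Thin wrapper wiring the pipeline modules to shell usage; see
#' `inst/scripts/nbscreen` for the Rscript launcher. Returns (rather than
#' calls `quit()` with) the exit code so it stays testable: 0 on success, 2
#' on usage errors, 1 on validation/processing errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  if (is.null(parsed)) { message(cli_usage()); return(invisible(2L)) }
  sub <- parsed$sub; opts <- parsed$opts
  code <- tryCatch({
    switch(sub,
      replay = {
        if (is.null(opts$method) || is.null(opts$strategy)) {
          message(cli_usage()); return(invisible(2L))
        }
        fx <- if (!is.null(opts$fixture)) load_detection_fixture(opts$fixture)
              else detection_fixture()$fixture
        counts <- replay_detection(fx, opts$method, opts$strategy)
        cat(sprintf("method=%s strategy=%s tp=%d fn=%d evaluable=%d\n",
                    opts$method, opts$strategy, counts$tp, counts$fn,
                    counts$n_evaluable))
        if (!is.null(opts$out)) write_report(counts = counts, path = opts$out)
        0L
      },
      simulate = {
        if (is.null(opts$n) || is.null(opts$out_dir)) {
          message(cli_usage()); return(invisible(2L))
        }
        seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
        cfg <- sim_config(seed = seed,
                          n_genes = as.integer(
                            if (is.null(opts$n_genes)) 100L else opts$n_genes))
        objs <- generate_panel(cfg)
        bg <- generate_background_cohort(cfg, objs, as.integer(opts$n))
        dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_annotated_vcf(bg$variants,
                            file.path(opts$out_dir, "cohort.vcf"))
        utils::write.table(objs$panel, file.path(opts$out_dir, "panel.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(objs$kb),
                           file.path(opts$out_dir, "kb.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(bg$truth, file.path(opts$out_dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      screen = {
        if (is.null(opts$vcf) || is.null(opts$panel) || is.null(opts$kb)) {
          message(cli_usage()); return(invisible(2L))
        }
        cfg <- if (!is.null(opts$config)) read_config(opts$config)
               else pipeline_config()
        strategy <- if (!is.null(opts$strategy)) opts$strategy
                    else cfg$strategy
        panel <- panel_table(utils::read.delim(opts$panel,
                                               stringsAsFactors = FALSE))
        kb <- load_knowledgebase(opts$kb)
        review <- if (!is.null(opts$review)) load_review_table(opts$review)
                  else NULL
        variants <- read_annotated_vcf(opts$vcf, cfg)
        cands <- apply_review(strict_lp_filter(variants, kb, NULL, cfg),
                              review)
        if (strategy == "extended")
          cands <- vus_extension(cands, variants, kb, panel, cfg)
        results <- screen_cohort(cands, panel, strategy,
                                 sample_ids = unique(variants$sample_id))
        tab <- screen_results_table(results)
        pos <- unique(tab$sample_id[tab$overall == "positive"])
        cat(sprintf("samples=%d positive=%d\n",
                    length(unique(variants$sample_id)), length(pos)))
        if (!is.null(opts$out)) write_report(results = results,
                                             path = opts$out)
        0L
      },
      funnel = {
        if (is.null(opts$vcf) || is.null(opts$panel) || is.null(opts$kb)) {
          message(cli_usage()); return(invisible(2L))
        }
        cfg <- if (!is.null(opts$config)) read_config(opts$config)
               else pipeline_config()
        panel <- panel_table(utils::read.delim(opts$panel,
                                               stringsAsFactors = FALSE))
        kb <- load_knowledgebase(opts$kb)
        review <- if (!is.null(opts$review)) load_review_table(opts$review)
                  else NULL
        variants <- read_annotated_vcf(opts$vcf, cfg)
        fr <- run_funnel(variants, panel, kb, NULL, review, cfg)
        rep <- funnel_report(fr)
        cat(paste(sprintf("%-24s %8d %6s", rep$stage, rep$count,
                          rep$percent), collapse = "\n"), "\n")
        if (!is.null(opts$out))
          utils::write.table(rep, paste0(opts$out, ".tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
        0L
      },
      { message(cli_usage()); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(as.integer(code))
}
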