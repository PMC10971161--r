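# Synthetic panels, knowledge bases and cohorts: patients with planted causal
# genotypes per mode of inheritance, variant-free/benign negative controls,
# and a background cohort whose funnel proportions emulate a large presumed-
# healthy population. Everything is deterministic under a fixed seed.

GENOTYPE_TYPES <- c("hom_lp", "compound_het", "lp_plus_vus", "hom_vus",
                    "xlr_hemi", "ad_het", "cnv_plus_snv")

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is assessed under:
#' a 100-gene recessive-dominated panel; heterozygous VAF noise of
#' Normal(0.5, 0.05) clipped to 0.35-0.65 so window-edge behaviour is a
#' config choice rather than random; a per-individual carrier burden of
#' Poisson(0.28) heterozygous (L)P alleles in autosomal-recessive genes and
#' Poisson(2.4) coding-region noise variants, which together put about 7% of
#' background individuals at zero panel SNVs, about 70% at SNVs-but-no-(L)P,
#' and about 21% at a single heterozygous (L)P in a recessive gene; a
#' 3-in-4833 rate of homozygous (L)P genotypes in mild-phenotype genes; and a
#' patient causal-genotype mix dominated by compound heterozygotes and
#' homozygotes with a small homozygous-VUS fraction.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of panel genes.
#' @param moi_mix Named proportions over AD/AR/XLR (sum 1).
#' @param per_gene_variant_rate Mean noise variants per individual per gene
#'   (Poisson); the cohort-wide mean is `n_genes * per_gene_variant_rate`.
#' @param class_mix Named proportions over noise-variant classes
#'   `lp`/`vus`/`benign`/`unlisted` (sum 1).
#' @param af_rare_range Log-uniform range for rare-allele population AFs.
#' @param af_common_range Uniform range for common-allele population AFs.
#' @param vaf_noise_sd SD of heterozygous VAF around 0.5.
#' @param vaf_clip Clipping bounds for heterozygous VAFs.
#' @param carrier_rate Poisson rate of heterozygous (L)P carrier alleles per
#'   individual (AR genes).
#' @param hom_lp_rate Probability of a homozygous (L)P in a mild-phenotype
#'   gene in a background individual.
#' @param patient_moi_fractions Named proportions over causal genotype types
#'   (see `GENOTYPE_TYPES`; sum 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       moi_mix = c(AD = 0.05, AR = 0.89, XLR = 0.06),
                       per_gene_variant_rate = 0.024,
                       class_mix = c(lp = 0, vus = 0.25, benign = 0.60,
                                     unlisted = 0.15),
                       af_rare_range = c(1e-6, 5e-3),
                       af_common_range = c(0.01, 0.5),
                       vaf_noise_sd = 0.05,
                       vaf_clip = c(0.35, 0.65),
                       carrier_rate = 0.28,
                       hom_lp_rate = 3 / 4833,
                       patient_moi_fractions = c(hom_lp = 0.23,
                                                 compound_het = 0.40,
                                                 lp_plus_vus = 0.19,
                                                 hom_vus = 0.06,
                                                 xlr_hemi = 0.04,
                                                 ad_het = 0.04,
                                                 cnv_plus_snv = 0.04)) {
  stopifnot(abs(sum(moi_mix) - 1) < 1e-8,
            abs(sum(class_mix) - 1) < 1e-8,
            abs(sum(patient_moi_fractions) - 1) < 1e-8,
            all(names(patient_moi_fractions) %in% GENOTYPE_TYPES))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 moi_mix = moi_mix,
                 per_gene_variant_rate = per_gene_variant_rate,
                 class_mix = class_mix, af_rare_range = af_rare_range,
                 af_common_range = af_common_range,
                 vaf_noise_sd = vaf_noise_sd, vaf_clip = vaf_clip,
                 carrier_rate = carrier_rate, hom_lp_rate = hom_lp_rate,
                 patient_moi_fractions = patient_moi_fractions),
            class = "sim_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# an individual carries any given variant at most once
dedupe_variants <- function(v) {
  v[!duplicated(paste(v$sample_id, v$variant_key)), , drop = FALSE]
}

het_vaf <- function(n, config) {
  clip(stats::rnorm(n, 0.5, config$vaf_noise_sd),
       config$vaf_clip[1], config$vaf_clip[2])
}

hom_vaf <- function(n) clip(stats::rnorm(n, 0.98, 0.01), 0.9, 1)

draw_af <- function(n, rare, config) {
  out <- numeric(n)
  r <- config$af_rare_range
  out[rare] <- exp(stats::runif(sum(rare), log(r[1]), log(r[2])))
  cmn <- config$af_common_range
  out[!rare] <- stats::runif(sum(!rare), cmn[1], cmn[2])
  out
}

#' Generate a synthetic gene panel, transcript models and knowledge base
#'
#' Builds `n_genes` panel entries with toy transcript models (2-10 exons,
#' both strands, UTRs at both ends) and a knowledge base seeded per gene with
#' (likely) pathogenic, VUS and benign entries at coding positions. X-linked
#' recessive genes are placed on chromosome X; three AR genes are flagged
#' mild-phenotype (consumed only by reports). Also returns the site catalogue
#' the cohort generators draw variants from.
#'
#' @param config [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List `panel`, `transcripts`, `kb`, `sites`. `sites` has one row
#'   per plantable coding position with its role (`lp`/`vus`/`benign`/
#'   `unlisted`), alleles, `csq` token and population AF.
#' @export
generate_panel <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_genes
  moi <- sample(names(config$moi_mix), n, replace = TRUE,
                prob = config$moi_mix)
  chrom <- ifelse(moi == "XLR", "X",
                  as.character(sample(1:22, n, replace = TRUE)))
  gene <- sprintf("GENE%03d", seq_len(n))
  mild <- rep(FALSE, n)
  ar_idx <- which(moi == "AR")
  mild[ar_idx[seq_len(min(3L, length(ar_idx)))]] <- TRUE
  panel <- panel_table(data.frame(gene = gene, moi = moi,
                                  disorder = paste0("disorder_", gene),
                                  chrom = chrom, mild_phenotype = mild,
                                  stringsAsFactors = FALSE))
  bases <- c("A", "C", "G", "T")
  txs <- vector("list", n)
  site_rows <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:10, 1)
    ex_len <- sample(90:250, n_ex, replace = TRUE)
    introns <- sample(100:2000, n_ex - 1, replace = TRUE)
    start0 <- i * 1000000L
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- start0
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      if (e < n_ex) pos <- ends[e] + introns[e] + 1L
    }
    strand <- sample(c("+", "-"), 1)
    cds_start <- starts[1] + sample(10:40, 1)
    cds_end <- ends[n_ex] - sample(10:40, 1)
    tx <- transcript_model(paste0("TX_", gene[i], ".1"), gene[i], strand,
                           starts, ends, cds_start, cds_end, is_mane = TRUE)
    txs[[i]] <- tx
    # coding positions eligible for planted variants: inside the CDS and not
    # in the first/last 5 bp of an exon, so classes stay exonic
    cds_pos <- unlist(lapply(seq_len(n_ex), function(e) {
      lo <- max(starts[e] + 5L, cds_start)
      hi <- min(ends[e] - 5L, cds_end)
      if (lo > hi) integer() else lo:hi
    }))
    n_lp <- 4L; n_vus <- 4L; n_benign <- 3L; n_unlisted <- 4L
    n_sites <- n_lp + n_vus + n_benign + n_unlisted
    pos_pick <- sort(sample(cds_pos, n_sites))
    role <- sample(rep(c("lp", "vus", "benign", "unlisted"),
                       c(n_lp, n_vus, n_benign, n_unlisted)))
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    csq <- ifelse(role == "lp",
                  sample(c("missense", "stop_gained", "frameshift"), n_sites,
                         replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                  sample(c("missense", "synonymous"), n_sites, replace = TRUE,
                         prob = c(0.7, 0.3)))
    af <- draw_af(n_sites, rare = role != "benign", config)
    site_rows[[i]] <- data.frame(gene = gene[i], chrom = chrom[i],
                                 pos = pos_pick, ref = ref, alt = alt,
                                 transcript_id = tx$transcript_id,
                                 role = role, csq = csq, population_af = af,
                                 stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  kb_sites <- sites[sites$role %in% c("lp", "vus", "benign"), , drop = FALSE]
  classification <- ifelse(kb_sites$role == "lp",
                           sample(c("P", "LP"), nrow(kb_sites),
                                  replace = TRUE),
                           ifelse(kb_sites$role == "vus", "VUS",
                                  sample(c("B", "LB"), nrow(kb_sites),
                                         replace = TRUE)))
  kb <- knowledge_base(data.frame(chrom = kb_sites$chrom, pos = kb_sites$pos,
                                  ref = kb_sites$ref, alt = kb_sites$alt,
                                  source = sample(KB_SOURCES, nrow(kb_sites),
                                                  replace = TRUE),
                                  classification = classification,
                                  release = "sim-1",
                                  stringsAsFactors = FALSE))
  list(panel = panel, transcripts = transcript_set(txs), kb = kb,
       sites = sites)
}

site_to_variant <- function(site, sample_id, vaf, zygosity) {
  data.frame(sample_id = sample_id, chrom = site$chrom, pos = site$pos,
             end = site$pos, ref = site$ref, alt = site$alt,
             gene = site$gene, transcript_id = site$transcript_id,
             hgvs_c = NA_character_, hgvs_p = NA_character_,
             var_type = ifelse(site$csq == "frameshift", "indel", "SNV"),
             csq = site$csq, population_af = site$population_af,
             vaf = vaf, zygosity = zygosity, coverage_ok = TRUE,
             raw_only = FALSE, in_cis = FALSE, stringsAsFactors = FALSE)
}

noise_variants <- function(sites, sample_ids, n_per_sample, config) {
  total <- sum(n_per_sample)
  if (total == 0L)
    return(NULL)
  pool_role <- sample(c("vus", "benign", "unlisted"), total, replace = TRUE,
                      prob = config$class_mix[c("vus", "benign", "unlisted")] /
                        sum(config$class_mix[c("vus", "benign", "unlisted")]))
  rows <- integer(total)
  for (r in c("vus", "benign", "unlisted")) {
    k <- pool_role == r
    pool <- which(sites$role == r)
    rows[k] <- sample(pool, sum(k), replace = TRUE)
  }
  picked <- sites[rows, , drop = FALSE]
  site_to_variant(picked, rep(sample_ids, n_per_sample),
                  het_vaf(total, config), "het")
}

#' Generate one synthetic patient
#'
#' Plants a causal genotype of the requested type (drawn from
#' `patient_moi_fractions` when not given) in a compatible panel gene, then
#' adds background noise variants. The homozygous-VUS type emulates the known
#' screening limitation: such patients are false negative under both
#' strategies.
#'
#' @param config [sim_config()].
#' @param panel_objs Result of [generate_panel()].
#' @param sample_id Sample identifier.
#' @param genotype_type One of `hom_lp`, `compound_het`, `lp_plus_vus`,
#'   `hom_vus`, `xlr_hemi`, `ad_het`, `cnv_plus_snv`, or `NULL` to draw.
#' @return List `variants` (variant table rows), `truth` (one-row truth
#'   record with `genotype_type` and `known_keys`).
#' @export
generate_patient <- function(config, panel_objs, sample_id,
                             genotype_type = NULL) {
  panel <- panel_objs$panel
  sites <- panel_objs$sites
  txs <- panel_objs$transcripts
  if (is.null(genotype_type))
    genotype_type <- sample(names(config$patient_moi_fractions), 1,
                            prob = config$patient_moi_fractions)
  need_moi <- switch(genotype_type, xlr_hemi = "XLR", ad_het = "AD", "AR")
  genes <- panel$gene[panel$moi == need_moi]
  if (genotype_type == "compound_het") {
    lp_per_gene <- table(sites$gene[sites$role == "lp"])
    genes <- intersect(genes, names(lp_per_gene)[lp_per_gene >= 2])
  }
  if (!length(genes))
    stop("no panel gene compatible with genotype type ", genotype_type,
         call. = FALSE)
  g <- sample(genes, 1)
  lp_sites <- sites[sites$gene == g & sites$role == "lp", , drop = FALSE]
  vus_sites <- sites[sites$gene == g & sites$role == "vus", , drop = FALSE]
  planted <- switch(genotype_type,
    hom_lp = site_to_variant(lp_sites[sample(nrow(lp_sites), 1), ],
                             sample_id, hom_vaf(1), "hom"),
    compound_het = {
      two <- lp_sites[sample(nrow(lp_sites), 2), ]
      site_to_variant(two, sample_id, het_vaf(2, config), "het")
    },
    lp_plus_vus = rbind(
      site_to_variant(lp_sites[sample(nrow(lp_sites), 1), ], sample_id,
                      het_vaf(1, config), "het"),
      site_to_variant(vus_sites[sample(nrow(vus_sites), 1), ], sample_id,
                      het_vaf(1, config), "het")),
    hom_vus = site_to_variant(vus_sites[sample(nrow(vus_sites), 1), ],
                              sample_id, hom_vaf(1), "hom"),
    xlr_hemi = site_to_variant(lp_sites[sample(nrow(lp_sites), 1), ],
                               sample_id, hom_vaf(1), "hemi"),
    ad_het = site_to_variant(lp_sites[sample(nrow(lp_sites), 1), ],
                             sample_id, het_vaf(1, config), "het"),
    cnv_plus_snv = {
      tx <- txs[[attr(txs, "gene_index")[[g]]]]
      snv <- site_to_variant(lp_sites[sample(nrow(lp_sites), 1), ],
                             sample_id, hom_vaf(1), "hemi")
      cnv <- snv
      cnv$pos <- min(tx$exon_starts) - 1000L
      cnv$end <- max(tx$exon_ends) + 1000L
      cnv$ref <- NA_character_; cnv$alt <- NA_character_
      cnv$var_type <- "CNV_del"; cnv$csq <- NA_character_
      cnv$population_af <- 0; cnv$vaf <- 0.5; cnv$zygosity <- "het"
      rbind(cnv, snv)
    })
  n_noise <- stats::rpois(1, config$n_genes * config$per_gene_variant_rate)
  noise <- noise_variants(sites, sample_id, n_noise, config)
  variants <- dedupe_variants(variant_table(rbind(planted, noise)))
  truth <- data.frame(sample_id = sample_id, cohort_role = "patient",
                      diagnosis_gene = g, genotype_type = genotype_type,
                      known_keys = paste(variant_table(planted)$variant_key,
                                         collapse = ";"),
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

#' Generate a synthetic background cohort
#'
#' Individuals carry no planted disease genotype: a Poisson
#' (`n_genes * per_gene_variant_rate`) number of coding noise variants, a
#' Poisson(`carrier_rate`) number of heterozygous (L)P carrier alleles in
#' random AR genes, and with probability `hom_lp_rate` one homozygous (L)P in
#' a mild-phenotype gene. With shipped defaults the expected funnel
#' proportions are roughly 7% no-SNV, 70% SNVs-but-no-(L)P and 21% single
#' heterozygous (L)P.
#'
#' @param config [sim_config()].
#' @param panel_objs Result of [generate_panel()].
#' @param n Cohort size.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param id_prefix Sample-id prefix.
#' @return List `variants` (cohort variant table), `truth`, `sample_ids`.
#' @export
generate_background_cohort <- function(config, panel_objs, n,
                                       seed = config$seed,
                                       id_prefix = "BG") {
  set.seed(seed)
  panel <- panel_objs$panel
  sites <- panel_objs$sites
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  n_noise <- stats::rpois(n, config$n_genes * config$per_gene_variant_rate)
  noise <- noise_variants(sites, ids, n_noise, config)
  n_carrier <- stats::rpois(n, config$carrier_rate)
  carrier <- NULL
  if (sum(n_carrier) > 0L) {
    ar_lp <- sites[sites$role == "lp" &
                     sites$gene %in% panel$gene[panel$moi == "AR"], ,
                   drop = FALSE]
    rows <- sample(nrow(ar_lp), sum(n_carrier), replace = TRUE)
    carrier <- site_to_variant(ar_lp[rows, ], rep(ids, n_carrier),
                               het_vaf(sum(n_carrier), config), "het")
  }
  hom <- NULL
  hom_pick <- stats::runif(n) < config$hom_lp_rate
  if (any(hom_pick)) {
    mild_lp <- sites[sites$role == "lp" &
                       sites$gene %in% panel$gene[panel$mild_phenotype], ,
                     drop = FALSE]
    rows <- sample(nrow(mild_lp), sum(hom_pick), replace = TRUE)
    hom <- site_to_variant(mild_lp[rows, ], ids[hom_pick],
                           hom_vaf(sum(hom_pick)), "hom")
  }
  pieces <- Filter(Negate(is.null), list(noise, carrier, hom))
  variants <- if (length(pieces))
    dedupe_variants(variant_table(do.call(rbind, pieces))) else
    variant_table(data.frame(sample_id = character(), chrom = character(),
                             pos = integer(), gene = character(),
                             var_type = character(), population_af = numeric(),
                             vaf = numeric(), zygosity = character(),
                             stringsAsFactors = FALSE))
  truth <- data.frame(sample_id = ids, cohort_role = "background",
                      diagnosis_gene = NA_character_,
                      genotype_type = NA_character_, known_keys = "",
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth, sample_ids = ids)
}

#' Generate a mixed synthetic cohort of patients and controls
#'
#' Patients get a planted causal genotype (per `patient_moi_fractions` unless
#' `genotype_types` pins them); controls get noise and carrier variants only.
#'
#' @param config [sim_config()].
#' @param panel_objs Result of [generate_panel()].
#' @param n_patients,n_controls Cohort composition.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param genotype_types Optional vector of genotype types recycled over
#'   patients.
#' @return List `variants`, `truth`, `sample_ids`.
#' @export
generate_cohort <- function(config, panel_objs, n_patients, n_controls = 0L,
                            seed = config$seed, genotype_types = NULL) {
  set.seed(seed)
  pieces <- list(); truths <- list()
  for (i in seq_len(n_patients)) {
    gt <- if (is.null(genotype_types)) NULL else
      genotype_types[(i - 1L) %% length(genotype_types) + 1L]
    p <- generate_patient(config, panel_objs, sprintf("PT%04d", i), gt)
    pieces[[length(pieces) + 1L]] <- p$variants
    truths[[length(truths) + 1L]] <- p$truth
  }
  ctrl_ids <- character()
  if (n_controls > 0L) {
    bg <- generate_background_cohort(config, panel_objs, n_controls,
                                     seed = sample.int(2^30, 1),
                                     id_prefix = "CT")
    bg$truth$cohort_role <- "control"
    pieces[[length(pieces) + 1L]] <- bg$variants
    truths[[length(truths) + 1L]] <- bg$truth
    ctrl_ids <- bg$sample_ids
  }
  variants <- do.call(rbind, pieces)
  rownames(variants) <- NULL
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(variants = variants, truth = truth,
       sample_ids = c(sprintf("PT%04d", seq_len(n_patients)), ctrl_ids))
}
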