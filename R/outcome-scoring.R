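# Outcome scoring: confusion counts against diagnostic truth, and replay of
# the shipped per-sample, per-method detection-status fixture that reproduces
# the published counts.

DETECTION_STATUSES <- c("LP_surfaced", "VUS_surfaced", "not_surfaced",
                        "no_data")
NGS_METHODS <- c("tNGS", "WES", "WGS")

#' Load a detection-status fixture from TSV
#'
#' One row per known diagnostic variant of a patient sample, with its
#' surfaced status per sequencing method: `LP_surfaced` (passed the strict
#' (L)P filter), `VUS_surfaced` (surfaced only through the VUS extension),
#' `not_surfaced`, or `no_data` (the sample failed that method).
#'
#' @param path TSV with columns `sample_id`, `gene`, `variant_key`, `hgvs_c`,
#'   `zygosity`, `status_tNGS`, `status_WES`, `status_WGS`.
#' @return Validated data frame of class `detection_fixture`.
#' @export
load_detection_fixture <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "gene", "variant_key", "zygosity",
            paste0("status_", NGS_METHODS))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fixture missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (m in NGS_METHODS) {
    col <- df[[paste0("status_", m)]]
    if (any(!col %in% DETECTION_STATUSES))
      stop("unknown detection status for method ", m, call. = FALSE)
  }
  class(df) <- c("detection_fixture", "data.frame")
  df
}

#' Shipped patient detection fixture
#'
#' The package's bundled encoding of the 47 sequenced patient samples'
#' known diagnostic variants and their per-method surfaced statuses, together
#' with the reasons annotated for missed variants.
#'
#' @return List with `fixture` (a detection fixture), `truth` (a truth
#'   table, see [truth_table()]) and `fn_causes` (data frame `sample_id`,
#'   `method`, `cause`).
#' @export
detection_fixture <- function() {
  dir <- system.file("extdata", package = "nbscreen")
  list(fixture = load_detection_fixture(file.path(dir,
                                                  "detection_fixture.tsv")),
       truth = load_truth_table(file.path(dir, "detection_truth.tsv")),
       fn_causes = utils::read.delim(file.path(dir, "fn_causes.tsv"),
                                     stringsAsFactors = FALSE))
}

#' Construct/validate a diagnostic-truth table
#'
#' @param df Data frame with columns `sample_id`, `cohort_role`
#'   (`patient`/`control`/`background`) and, for patients, `diagnosis_gene`.
#' @return Validated data frame.
#' @export
truth_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort_role") %in% names(df)))
    stop("truth table needs sample_id and cohort_role", call. = FALSE)
  if (!"diagnosis_gene" %in% names(df))
    df$diagnosis_gene <- rep(NA_character_, nrow(df))
  if (any(!df$cohort_role %in% c("patient", "control", "background")))
    stop("unknown cohort_role token", call. = FALSE)
  if (any(df$cohort_role == "patient" & is.na(df$diagnosis_gene)))
    stop("patients need a diagnosis_gene", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample in truth table", call. = FALSE)
  df
}

#' Load a truth table from TSV
#' @param path TSV with the [truth_table()] columns.
#' @return Validated truth table.
#' @export
load_truth_table <- function(path) {
  truth_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_evaluable = as.integer(tp + fp + fn + tn)),
            class = "confusion_counts")
}

#' Score screen results against diagnostic truth
#'
#' A patient whose screen is positive with a positive finding in the
#' diagnosis gene is a true positive; a patient who is not positive, or
#' positive only in another gene, is a false negative (the off-target
#' positive is flagged as an incidental finding). A control or background
#' individual positive anywhere is a false positive; otherwise a true
#' negative.
#'
#' @param results List of screen results from [screen_cohort()]; one per
#'   truth record.
#' @param truth [truth_table()].
#' @return List of class `confusion_counts` with an `incidentals` attribute
#'   (data frame of off-diagnosis positives).
#' @export
score_cohort <- function(results, truth) {
  truth <- truth_table(truth)
  ids <- vapply(results, `[[`, character(1), "sample_id")
  i <- match(ids, truth$sample_id)
  if (any(is.na(i)))
    stop("screen result without a matching truth record", call. = FALSE)
  tp <- fp <- fn <- tn <- 0L
  incid <- list()
  for (k in seq_along(results)) {
    res <- results[[k]]
    role <- truth$cohort_role[i[k]]
    pos_genes <- names(Filter(function(f) f$call == "positive", res$findings))
    if (role == "patient") {
      dg <- truth$diagnosis_gene[i[k]]
      if (res$overall == "positive" && dg %in% pos_genes) tp <- tp + 1L
      else {
        fn <- fn + 1L
        off <- setdiff(pos_genes, dg)
        if (length(off))
          incid[[length(incid) + 1L]] <-
            data.frame(sample_id = res$sample_id, gene = off,
                       stringsAsFactors = FALSE)
      }
    } else {
      if (res$overall == "positive") fp <- fp + 1L else tn <- tn + 1L
    }
  }
  out <- confusion_counts(tp = tp, fp = fp, fn = fn, tn = tn)
  attr(out, "incidentals") <- if (length(incid)) do.call(rbind, incid) else
    data.frame(sample_id = character(), gene = character(),
               stringsAsFactors = FALSE)
  out
}

#' Replay the detection fixture for one method and strategy
#'
#' A sample-method pair is evaluable iff not every known-variant status is
#' `no_data`. Under the strict strategy a sample is counted true positive
#' when every known variant is surfaced as (likely) pathogenic; under the
#' extended strategy when every known variant is surfaced as (L)P or VUS with
#' at least one (L)P. All other evaluable samples are false negatives.
#' Samples with a single known variant are judged on that variant alone.
#'
#' @param fixture A detection fixture ([load_detection_fixture()]).
#' @param method One of `"tNGS"`, `"WES"`, `"WGS"`.
#' @param strategy `"strict"` or `"extended"`.
#' @return `confusion_counts` (tn/fp zero: the fixture holds patients only),
#'   with attributes `tp_samples` and `fn_samples`.
#' @export
replay_detection <- function(fixture, method = NGS_METHODS,
                             strategy = c("strict", "extended")) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  col <- paste0("status_", method)
  by_sample <- split(fixture[[col]], fixture$sample_id)
  evaluable <- vapply(by_sample, function(st) !all(st == "no_data"),
                      logical(1))
  positive <- vapply(by_sample, function(st) {
    if (all(st == "no_data")) return(FALSE)
    if (strategy == "strict") all(st == "LP_surfaced")
    else all(st %in% c("LP_surfaced", "VUS_surfaced")) &&
      any(st == "LP_surfaced")
  }, logical(1))
  tp_samples <- names(by_sample)[evaluable & positive]
  fn_samples <- names(by_sample)[evaluable & !positive]
  out <- confusion_counts(tp = length(tp_samples), fn = length(fn_samples))
  attr(out, "tp_samples") <- tp_samples
  attr(out, "fn_samples") <- fn_samples
  out
}

#' Report false-negative samples with the reason each variant was missed
#'
#' @param fixture A detection fixture.
#' @param fn_causes Data frame `sample_id`, `method`, `cause` (per-method
#'   annotations of why variants were missed).
#' @param method,strategy As in [replay_detection()].
#' @return Data frame `sample_id`, `missed_variants`, `cause` for every false
#'   negative of the chosen method and strategy; zero rows when there are
#'   none.
#' @export
fn_cause_report <- function(fixture, fn_causes, method = NGS_METHODS,
                            strategy = c("strict", "extended")) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  counts <- replay_detection(fixture, method, strategy)
  fns <- attr(counts, "fn_samples")
  if (!length(fns))
    return(data.frame(sample_id = character(), missed_variants = character(),
                      cause = character(), stringsAsFactors = FALSE))
  col <- paste0("status_", method)
  bad_status <- if (strategy == "strict")
    c("VUS_surfaced", "not_surfaced", "no_data") else
    c("not_surfaced", "no_data")
  rows <- lapply(fns, function(sid) {
    sub <- fixture[fixture$sample_id == sid, , drop = FALSE]
    missed <- sub$variant_key[sub[[col]] %in% bad_status]
    cause <- fn_causes$cause[fn_causes$sample_id == sid &
                               fn_causes$method == method]
    data.frame(sample_id = sid,
               missed_variants = paste(missed, collapse = ";"),
               cause = if (length(cause)) cause[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
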