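#' Truth-set construction and possible-error-rate estimation
#'
#' The reference platform (deep targeted sequencing) defines a *truth set*:
#' its calls with mutant allele frequency at or above a cutoff (default 10%)
#' are treated as possible true positives, since such calls are highly
#' reproducible between technical replicates. Against this truth set a
#' database callset yields:
#' \describe{
#'   \item{P-TP}{database calls confirmed in the truth set / database calls.}
#'   \item{P-FP}{database-only calls / database calls.}
#'   \item{adjusted P-FP}{as P-FP, but database-only calls that the reference
#'     detects at sub-cutoff frequency are reclassified as possibly true
#'     ("rescued") and removed from the numerator.}
#'   \item{positive identification rate}{truth calls recovered by the
#'     database / truth calls.}
#'   \item{P-FN}{1 minus the positive identification rate.}
#' }
#' All rates are "possible" rates, conditioned on the high-frequency truth
#' assumption rather than on an absolute gold standard.
#'
#' @name error_rates
NULL

#' Build a truth set from a reference callset
#'
#' @param reference a `fnscope_callset` whose calls carry defined `maf`.
#' @param maf_cutoff inclusive high-frequency cutoff in (0, 1), default 0.10.
#' @return a `fnscope_truth_set`: list with `truth_calls` (high-frequency
#'   subset), `full_reference` (all reference calls, used for low-frequency
#'   rescue) and `maf_cutoff`.
#' @export
build_truth_set <- function(reference, maf_cutoff = 0.10) {
  stopifnot(is_callset(reference))
  if (!(maf_cutoff > 0 && maf_cutoff < 1)) {
    abort("maf_cutoff must be in (0, 1)", class = "fnscope_config_error")
  }
  maf <- reference$calls$maf
  if (nrow(reference$calls) > 0 && anyNA(maf)) {
    abort("reference calls must carry a defined maf",
          class = "fnscope_input_error")
  }
  truth <- subset_callset(reference, !is.na(maf) & maf >= maf_cutoff)
  truth$source_label <- paste0(reference$source_label, "_hmAF")
  structure(
    list(truth_calls = truth, full_reference = reference,
         maf_cutoff = maf_cutoff),
    class = "fnscope_truth_set"
  )
}

#' @export
print.fnscope_truth_set <- function(x, ...) {
  cat(sprintf("<fnscope_truth_set> %d truth calls (maf >= %g) of %d reference calls\n",
              callset_size(x$truth_calls), x$maf_cutoff,
              callset_size(x$full_reference)))
  invisible(x)
}

#' Possible error rates of a database callset against a truth set
#'
#' @param db a `fnscope_callset` (same key scheme as the truth set).
#' @param truth a [build_truth_set()] result.
#' @return a `fnscope_error_report`: list of counts (`n_db`, `n_truth`,
#'   `n_confirmed`, `n_db_only`, `n_rescued`), rates (`p_tp`, `p_fp`,
#'   `adjusted_p_fp`, `identification_rate`, `p_fn`), their percent renderings
#'   (half-up, one decimal), the false-negative key set `fn_keys`, and the
#'   database label. `p_tp + p_fp = 1` and `identification_rate + p_fn = 1`
#'   hold exactly.
#' @export
error_report <- function(db, truth) {
  stopifnot(is_callset(db), inherits(truth, "fnscope_truth_set"))
  check_same_scheme(db, truth$truth_calls)
  kdb <- make_key(db)
  ktruth <- make_key(truth$truth_calls)
  n_db <- length(kdb)
  n_truth <- length(ktruth)
  if (n_db == 0) {
    abort(sprintf("database callset '%s' is empty: P-TP/P-FP undefined",
                  db$source_label),
          class = "fnscope_undefined_rate_error")
  }
  if (n_truth == 0) {
    abort("truth set is empty: identification rate undefined",
          class = "fnscope_undefined_rate_error")
  }
  confirmed <- intersect(kdb, ktruth)
  db_only <- setdiff(kdb, ktruth)
  # rescue: database-only keys that the reference detects at sub-cutoff maf
  ref <- truth$full_reference
  kref <- make_key(ref)
  ref_maf <- ref$calls$maf
  low_ref <- kref[!is.na(ref_maf) & ref_maf > 0 & ref_maf < truth$maf_cutoff]
  rescued <- intersect(db_only, low_ref)
  n_confirmed <- length(confirmed)
  n_db_only <- length(db_only)
  n_rescued <- length(rescued)
  p_tp <- n_confirmed / n_db
  ident <- n_confirmed / n_truth
  structure(
    list(db_label = db$source_label,
         truth_label = truth$truth_calls$source_label,
         maf_cutoff = truth$maf_cutoff,
         n_db = n_db, n_truth = n_truth, n_confirmed = n_confirmed,
         n_db_only = n_db_only, n_rescued = n_rescued,
         p_tp = p_tp, p_fp = 1 - p_tp,
         adjusted_p_fp = (n_db_only - n_rescued) / n_db,
         identification_rate = ident, p_fn = 1 - ident,
         p_tp_pct = percent1(p_tp), p_fp_pct = percent1(1 - p_tp),
         adjusted_p_fp_pct = percent1((n_db_only - n_rescued) / n_db),
         identification_pct = percent1(ident), p_fn_pct = percent1(1 - ident),
         fn_keys = setdiff(ktruth, kdb),
         confirmed_keys = confirmed, rescued_keys = rescued),
    class = "fnscope_error_report"
  )
}

#' @export
print.fnscope_error_report <- function(x, ...) {
  cat(sprintf("<fnscope_error_report> %s vs %s (maf cutoff %g)\n",
              x$db_label, x$truth_label, x$maf_cutoff))
  cat(sprintf("  P-TP %s%% (%d/%d)   P-FP %s%% (%d/%d)   adjusted P-FP %s%% (%d/%d)\n",
              x$p_tp_pct, x$n_confirmed, x$n_db,
              x$p_fp_pct, x$n_db_only, x$n_db,
              x$adjusted_p_fp_pct, x$n_db_only - x$n_rescued, x$n_db))
  cat(sprintf("  identification %s%% (%d/%d)   P-FN %s%% (%d/%d)\n",
              x$identification_pct, x$n_confirmed, x$n_truth,
              x$p_fn_pct, x$n_truth - x$n_confirmed, x$n_truth))
  invisible(x)
}

#' Combine database callsets by key union
#'
#' Takes the union of the callsets' keys; for keys present in several
#' sources, the record from the first source listing it is kept.
#'
#' @param dbs non-empty list of `fnscope_callset`s with one key scheme.
#' @param label source label of the combined callset.
#' @return a `fnscope_callset`.
#' @export
combine_callsets <- function(dbs, label) {
  if (length(dbs) == 0) {
    abort("combine_callsets needs at least one callset",
          class = "fnscope_config_error")
  }
  stopifnot(all(vapply(dbs, is_callset, logical(1))))
  for (d in dbs[-1]) check_same_scheme(dbs[[1]], d)
  scheme <- dbs[[1]]$key_scheme
  all_calls <- dplyr::bind_rows(lapply(dbs, function(d) d$calls))
  keys <- unlist(lapply(dbs, make_key))
  keep <- !duplicated(keys)
  out <- dbs[[1]]
  out$calls <- all_calls[keep, , drop = FALSE]
  out$source_label <- as.character(label)
  out$key_scheme <- scheme
  out
}

#' Gene-group configuration for false-negative profiling
#'
#' @param min_calls minimum truth calls for a gene to be grouped (default 5).
#' @param threshold per-gene P-FN at or above which the gene joins the high
#'   false-negative group (default 0.60).
#' @return a `fnscope_gene_group_config` list.
#' @export
gene_group_config <- function(min_calls = 5L, threshold = 0.60) {
  if (min_calls < 1) abort("min_calls must be >= 1",
                           class = "fnscope_config_error")
  if (!(threshold > 0 && threshold < 1)) {
    abort("threshold must be in (0, 1)", class = "fnscope_config_error")
  }
  structure(list(min_calls = as.integer(min_calls), threshold = threshold),
            class = "fnscope_gene_group_config")
}

#' Per-gene false-negative profiles
#'
#' For every gene present in the truth set, counts its truth calls and the
#' database calls confirmed in the truth set, and derives a per-gene P-FN
#' rate `clamp(1 - n_db / n_truth, 0, 1)`. Genes with at least `min_calls`
#' truth calls are assigned to the `high` group when their P-FN is at or
#' above `threshold`, otherwise `low`; genes below `min_calls` are
#' `excluded` from grouping.
#'
#' @param truth a [build_truth_set()] result.
#' @param db a `fnscope_callset`.
#' @param cfg a [gene_group_config()].
#' @return tibble with `gene`, `n_truth`, `n_db`, `p_fn`, `group`, sorted by
#'   descending `p_fn` then gene.
#' @export
gene_error_profiles <- function(truth, db, cfg = gene_group_config()) {
  stopifnot(inherits(truth, "fnscope_truth_set"), is_callset(db))
  check_same_scheme(db, truth$truth_calls)
  tcalls <- truth$truth_calls$calls
  ktruth <- make_key(truth$truth_calls)
  kdb <- make_key(db)
  confirmed <- ktruth %in% kdb
  n_truth <- table(tcalls$gene)
  n_db <- table(tcalls$gene[confirmed])
  genes <- sort(names(n_truth))
  nt <- as.integer(n_truth[genes])
  nd <- as.integer(ifelse(genes %in% names(n_db), n_db[genes], 0L))
  p_fn <- pmin(pmax(1 - nd / nt, 0), 1)
  group <- ifelse(nt < cfg$min_calls, "excluded",
                  ifelse(p_fn >= cfg$threshold, "high", "low"))
  tibble::tibble(gene = genes, n_truth = nt, n_db = nd,
                 p_fn = p_fn, group = group) %>%
    arrange(desc(.data$p_fn), .data$gene)
}

#' Select validation candidates among reference-only calls
#'
#' Implements in-silico candidate selection for orthogonal (e.g. PCR-Sanger)
#' validation: (i) truth calls found in none of the database callsets are
#' collected; (ii) genes are ranked by their count of such reference-only
#' calls, descending, ties broken alphabetically; (iii) all reference-only
#' calls in the top `top_n_genes` genes are selected; (iv) calls already
#' present in any confirmation callset (e.g. an updated database release) are
#' dropped, leaving the candidates that still need wet-lab validation.
#'
#' @param truth a [build_truth_set()] result.
#' @param dbs list of database `fnscope_callset`s.
#' @param confirm_sets list of confirmation `fnscope_callset`s (may be empty).
#' @param top_n_genes number of genes to take (default 10).
#' @return list with `candidates` (key vector), `selected` (keys before
#'   confirmation removal), `gene_ranking` (tibble of reference-only counts).
#' @export
select_validation_candidates <- function(truth, dbs, confirm_sets = list(),
                                         top_n_genes = 10L) {
  stopifnot(inherits(truth, "fnscope_truth_set"), top_n_genes >= 1)
  ktruth <- make_key(truth$truth_calls)
  kdb <- unique(unlist(lapply(dbs, make_key)))
  tcalls <- truth$truth_calls$calls
  ref_only <- !(ktruth %in% kdb)
  counts <- table(tcalls$gene[ref_only])
  ranking <- tibble::tibble(gene = names(counts),
                            n_ref_only = as.integer(counts)) %>%
    arrange(desc(.data$n_ref_only), .data$gene)
  top_genes <- head(ranking$gene, top_n_genes)
  selected <- ktruth[ref_only & tcalls$gene %in% top_genes]
  kconfirm <- unique(unlist(lapply(confirm_sets, make_key)))
  list(candidates = setdiff(selected, kconfirm),
       selected = selected,
       gene_ranking = ranking)
}
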