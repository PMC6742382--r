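#' Variant-selection filters
#'
#' The analysis callset is obtained from raw annotated calls by (1) dropping
#' silent/intronic/intergenic classes, (2) dropping known polymorphisms with
#' population allele frequency at or above a cutoff (missing frequency means
#' "novel", keep), and (3) removing probable germline contaminants: loci
#' recurring in more than a threshold fraction of samples, plus an explicit
#' locus blacklist.
#'
#' @name filtering
NULL

#' Filtering configuration
#'
#' @param keep_classes variant classes retained by the class filter. Default:
#'   exonic non-silent classes plus `Splice_Site`.
#' @param pop_af_max population allele-frequency cutoff; calls with
#'   `population_af >= pop_af_max` are removed (default 0.01, i.e. "common
#'   polymorphism").
#' @param recurrence_fraction fraction of samples above which a locus is
#'   flagged as a probable germline contaminant (default 0.80; the comparison
#'   is strict unless `recurrence_strict = FALSE`).
#' @param min_samples_for_recurrence minimum number of samples for recurrence
#'   flagging to be meaningful (default 10); below it no locus is flagged.
#' @param recurrence_strict flag only loci *strictly* above the fraction
#'   (default `TRUE`).
#' @param blacklist character vector of sample-agnostic locus keys (see
#'   [make_locus_key()]) to remove, or `NULL`.
#' @return a `fnscope_filter_config` list.
#' @export
filter_config <- function(keep_classes = DEFAULT_KEEP_CLASSES,
                          pop_af_max = 0.01,
                          recurrence_fraction = 0.80,
                          min_samples_for_recurrence = 10L,
                          recurrence_strict = TRUE,
                          blacklist = NULL) {
  if (!(pop_af_max > 0 && pop_af_max < 1)) {
    abort("pop_af_max must be in (0, 1)", class = "fnscope_config_error")
  }
  if (!(recurrence_fraction > 0 && recurrence_fraction <= 1)) {
    abort("recurrence_fraction must be in (0, 1]", class = "fnscope_config_error")
  }
  structure(
    list(keep_classes = as.character(keep_classes),
         pop_af_max = pop_af_max,
         recurrence_fraction = recurrence_fraction,
         min_samples_for_recurrence = as.integer(min_samples_for_recurrence),
         recurrence_strict = isTRUE(recurrence_strict),
         blacklist = blacklist),
    class = "fnscope_filter_config"
  )
}

subset_callset <- function(cs, keep) {
  cs$calls <- cs$calls[keep, , drop = FALSE]
  cs
}

#' Keep calls of selected variant classes
#'
#' @param calls a `fnscope_callset`.
#' @param keep_classes character vector of classes to retain.
#' @return filtered `fnscope_callset`.
#' @export
filter_by_class <- function(calls, keep_classes = DEFAULT_KEEP_CLASSES) {
  stopifnot(is_callset(calls))
  subset_callset(calls, calls$calls$variant_class %in% keep_classes)
}

#' Remove common polymorphisms by population allele frequency
#'
#' Calls with `population_af >= pop_af_max` are removed; calls with missing
#' population frequency are retained (a variant never reported in population
#' databases is treated as novel).
#'
#' @param calls a `fnscope_callset`.
#' @param pop_af_max cutoff fraction (default 0.01).
#' @return filtered `fnscope_callset`.
#' @export
filter_by_population_af <- function(calls, pop_af_max = 0.01) {
  stopifnot(is_callset(calls))
  paf <- calls$calls$population_af
  subset_callset(calls, is.na(paf) | paf < pop_af_max)
}

#' Flag recurrent (probable germline) loci
#'
#' A locus carried by more than `recurrence_fraction` of the samples in the
#' callset is almost certainly a germline polymorphism rather than a somatic
#' mutation, even when population databases do not report it. Flagging is
#' invariant under sample relabeling and returns an empty set when fewer than
#' `min_samples_for_recurrence` samples are present.
#'
#' @param calls a `fnscope_callset` spanning multiple samples.
#' @param cfg a [filter_config()].
#' @param n_samples total number of samples the callset represents; defaults
#'   to the number of distinct `sample_id` values observed (pass explicitly if
#'   some samples contributed no calls).
#' @return character vector of flagged sample-agnostic locus keys.
#' @export
flag_recurrent_germline <- function(calls, cfg = filter_config(),
                                    n_samples = NULL) {
  stopifnot(is_callset(calls))
  df <- calls$calls
  if (is.null(n_samples)) n_samples <- length(unique(df$sample_id))
  if (n_samples < cfg$min_samples_for_recurrence || nrow(df) == 0) {
    return(character(0))
  }
  locus <- make_locus_key(calls)
  carriers <- tapply(df$sample_id, locus, function(s) length(unique(s)))
  frac <- as.numeric(carriers) / n_samples
  hit <- if (cfg$recurrence_strict) frac > cfg$recurrence_fraction
         else frac >= cfg$recurrence_fraction
  sort(names(carriers)[hit])
}

#' Remove blacklisted loci
#'
#' Removes every call whose sample-agnostic locus key appears in the
#' blacklist, across all samples.
#'
#' @param calls a `fnscope_callset`.
#' @param blacklist character vector of locus keys (see [make_locus_key()] and
#'   [read_blacklist()]).
#' @return filtered `fnscope_callset`.
#' @export
apply_blacklist <- function(calls, blacklist) {
  stopifnot(is_callset(calls))
  if (length(blacklist) == 0) return(calls)
  subset_callset(calls, !(make_locus_key(calls) %in% blacklist))
}

#' Read a locus blacklist
#'
#' Reads a tab-separated blacklist with either genomic columns
#' (`chrom`, `pos`, `ref_allele`, `alt_allele`) or protein columns
#' (`gene`, `protein_change`), matching the callset's key scheme.
#'
#' @param path path to the TSV file.
#' @param key_scheme `"genomic"` or `"protein"`.
#' @return character vector of locus keys.
#' @export
read_blacklist <- function(path, key_scheme = c("genomic", "protein")) {
  key_scheme <- match.arg(key_scheme)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (key_scheme == "genomic") {
    need <- c("chrom", "pos", "ref_allele", "alt_allele")
    if (!all(need %in% names(df))) {
      abort("genomic blacklist needs columns chrom, pos, ref_allele, alt_allele",
            class = "fnscope_config_error")
    }
    paste(normalize_chrom(df$chrom), as.integer(df$pos),
          df$ref_allele, df$alt_allele, sep = "|")
  } else {
    need <- c("gene", "protein_change")
    if (!all(need %in% names(df))) {
      abort("protein blacklist needs columns gene, protein_change",
            class = "fnscope_config_error")
    }
    paste(df$gene, df$protein_change, sep = "|")
  }
}

#' Run the full variant-selection pipeline
#'
#' Applies, in order: class filter, population-allele-frequency filter,
#' recurrent-germline removal (loci flagged on the post-class-filter callset,
#' so silent/intronic calls never drive recurrence), and the explicit
#' blacklist. Returns the surviving callset together with a log attributing
#' each removed call to the first rule that removed it; the log always
#' satisfies `input = survivors + sum(removed)`.
#'
#' @param calls a `fnscope_callset`.
#' @param cfg a [filter_config()].
#' @param n_samples see [flag_recurrent_germline()].
#' @return list with elements `calls` (filtered `fnscope_callset`), `log`
#'   (tibble of per-rule removal counts) and `recurrent_loci` (flagged keys).
#' @export
run_filter_pipeline <- function(calls, cfg = filter_config(), n_samples = NULL) {
  stopifnot(is_callset(calls))
  n0 <- callset_size(calls)
  s1 <- filter_by_class(calls, cfg$keep_classes)
  n1 <- callset_size(s1)
  recurrent <- flag_recurrent_germline(s1, cfg, n_samples = n_samples)
  s2 <- filter_by_population_af(s1, cfg$pop_af_max)
  n2 <- callset_size(s2)
  s3 <- apply_blacklist(s2, recurrent)
  n3 <- callset_size(s3)
  s4 <- apply_blacklist(s3, cfg$blacklist)
  n4 <- callset_size(s4)
  log <- tibble::tibble(
    rule = c("variant_class", "population_af", "recurrent_germline", "blacklist"),
    removed = c(n0 - n1, n1 - n2, n2 - n3, n3 - n4)
  )
  stopifnot(n0 == n4 + sum(log$removed))
  list(calls = s4, log = log, recurrent_loci = recurrent)
}
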