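#' End-to-end study pipeline
#'
#' Chains filtering, truth-set construction, replicate concordance, error-rate
#' estimation, three-way comparison, gene profiling and stratified statistics
#' into one auditable report. Every percentage in the report is carried with
#' its numerator and denominator so each printed rate can be recomputed by
#' eye.
#'
#' @name workbench
NULL

#' Pipeline configuration
#'
#' Inputs may be given as `fnscope_callset` objects or as paths to
#' MAF-dialect files (read with [read_maf()] using the role name as source
#' label).
#'
#' @param replicates list of two replicate callsets/paths (deep reference
#'   sequencing, e.g. TarSeq1/TarSeq2). The first is also the reference that
#'   defines the truth set unless `reference` is given.
#' @param databases named list of database callsets/paths (at least one).
#' @param reference optional callset/path overriding `replicates[[1]]` as the
#'   truth-set reference.
#' @param updated_databases optional named list of later-release callsets,
#'   used as confirmation sets for validation-candidate selection.
#' @param filter a [filter_config()].
#' @param maf_cutoff truth-set allele-frequency cutoff (default 0.10).
#' @param gene_groups a [gene_group_config()].
#' @param cpg_islands optional BED3 path or tibble of CpG islands.
#' @param key_scheme comparison key scheme for all callsets.
#' @param top_n_genes genes taken by validation-candidate selection.
#' @return a `fnscope_run_config` list.
#' @export
run_config <- function(replicates, databases, reference = NULL,
                       updated_databases = list(),
                       filter = filter_config(), maf_cutoff = 0.10,
                       gene_groups = gene_group_config(),
                       cpg_islands = NULL,
                       key_scheme = c("genomic", "protein"),
                       top_n_genes = 10L) {
  key_scheme <- match.arg(key_scheme)
  if (length(replicates) < 2) {
    abort("two replicate callsets are required", class = "fnscope_config_error")
  }
  if (length(databases) < 1) {
    abort("at least one database callset is required",
          class = "fnscope_config_error")
  }
  if (is.null(names(databases)) || any(!nzchar(names(databases)))) {
    names(databases) <- paste0("DB", seq_along(databases))
  }
  if (anyDuplicated(names(databases))) {
    abort("database role labels must be unique", class = "fnscope_config_error")
  }
  structure(
    list(replicates = replicates, databases = databases,
         reference = reference, updated_databases = updated_databases,
         filter = filter, maf_cutoff = maf_cutoff,
         gene_groups = gene_groups, cpg_islands = cpg_islands,
         key_scheme = key_scheme, top_n_genes = as.integer(top_n_genes)),
    class = "fnscope_run_config"
  )
}

resolve_callset <- function(x, label, key_scheme) {
  if (is_callset(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort(paste0("input file for '", label, "' not found: ", x),
            class = "fnscope_config_error")
    }
    return(read_maf(x, source_label = label, key_scheme = key_scheme))
  }
  abort(paste0("input '", label, "' must be a callset or a file path"),
        class = "fnscope_config_error")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "fnscope_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and filter all sources; build the truth set from
#' the reference; replicate concordance (summary, binned consistency in both
#' modes, allele-frequency regressions); error-rate reports per database and
#' for the combined databases; three-way comparison and its
#' evolution-vs-error summary (two databases required); per-gene
#' false-negative profiles on the first database; CpG and gene-group
#' association tests (when CpG annotation is available); and
#' validation-candidate selection. Analysis is deterministic: no stage draws
#' random numbers.
#'
#' @param cfg a [run_config()].
#' @return a `fnscope_study_report` list; see the vignette for the layout.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "fnscope_run_config"))
  ks <- cfg$key_scheme
  reps <- with_stage("io", {
    labs <- names(cfg$replicates)
    if (is.null(labs)) labs <- c("TarSeq1", "TarSeq2")
    lapply(seq_along(cfg$replicates), function(i)
      resolve_callset(cfg$replicates[[i]], labs[i], ks))
  })
  dbs <- with_stage("io", {
    lapply(names(cfg$databases), function(nm)
      resolve_callset(cfg$databases[[nm]], nm, ks))
  })
  names(dbs) <- names(cfg$databases)
  updates <- with_stage("io", {
    lapply(names(cfg$updated_databases), function(nm)
      resolve_callset(cfg$updated_databases[[nm]], nm, ks))
  })
  reference <- if (is.null(cfg$reference)) reps[[1]]
               else with_stage("io", resolve_callset(cfg$reference, "reference", ks))

  islands <- with_stage("io", {
    if (is.null(cfg$cpg_islands)) NULL
    else if (is.data.frame(cfg$cpg_islands)) cfg$cpg_islands
    else read_bed3(cfg$cpg_islands)
  })
  annotate <- function(cs) if (is.null(islands)) cs else annotate_cpg(cs, islands)

  filt <- with_stage("filter", {
    # the reference is filtered first; loci it flags as recurrent germline
    # are blacklisted from every callset, since a database may carry a
    # germline contaminant in too few samples to flag it on its own
    rref <- run_filter_pipeline(annotate(reference), cfg$filter)
    db_filter <- cfg$filter
    db_filter$blacklist <- union(db_filter$blacklist, rref$recurrent_loci)
    out <- list()
    flog <- list()
    for (nm in names(dbs)) {
      r <- run_filter_pipeline(annotate(dbs[[nm]]), db_filter)
      out[[nm]] <- r$calls; flog[[nm]] <- r$log
    }
    list(dbs = out, reference = rref$calls, logs = flog,
         reference_log = rref$log, recurrent_loci = rref$recurrent_loci)
  })

  truth <- with_stage("truth", build_truth_set(filt$reference, cfg$maf_cutoff))

  replicate_concordance <- with_stage("concord", {
    cmp <- compare_callsets(reps[[1]], reps[[2]])
    list(
      summary = summarize_concordance(cmp),
      binned_either = binned_consistency(reps[[1]], reps[[2]], mode = "either"),
      binned_lowest = binned_consistency(reps[[1]], reps[[2]], mode = "lowest"),
      regression_hmaf = try_or_null(maf_regression(reps[[1]], reps[[2]],
                                                   "hmAF", cfg$maf_cutoff)),
      regression_low = try_or_null(maf_regression(reps[[1]], reps[[2]],
                                                  "low", cfg$maf_cutoff))
    )
  })

  rates <- with_stage("rates", {
    out <- lapply(filt$dbs, error_report, truth = truth)
    if (length(filt$dbs) >= 2) {
      combined <- combine_callsets(filt$dbs,
                                   paste(names(filt$dbs), collapse = "/"))
      out[[combined$source_label]] <- error_report(combined, truth)
    }
    out
  })

  db_concordance <- with_stage("concord", {
    if (length(filt$dbs) >= 2) {
      summarize_concordance(compare_callsets(filt$dbs[[1]], filt$dbs[[2]]))
    } else NULL
  })

  venn <- evo <- NULL
  if (length(filt$dbs) >= 2) {
    venn <- with_stage("concord",
      three_way_venn(filt$dbs[[1]], filt$dbs[[2]], truth$truth_calls))
    evo <- with_stage("concord",
      evolution_model_test(venn, roles = c(
        reference = truth$truth_calls$source_label,
        db1 = filt$dbs[[1]]$source_label,
        db2 = filt$dbs[[2]]$source_label)))
  }

  profiles <- with_stage("genes",
    gene_error_profiles(truth, filt$dbs[[1]], cfg$gene_groups))

  strat <- with_stage("strat", {
    have_flags <- !anyNA(truth$truth_calls$calls$in_cpg_island) &&
                  nrow(truth$truth_calls$calls) > 0
    if (!have_flags) NULL
    else {
      lapply(rates[names(filt$dbs)], function(rep) {
        list(cpg = cpg_fn_association(truth, rep),
             gene_group = group_fn_association(profiles, truth, rep))
      })
    }
  })

  candidates <- with_stage("candidates",
    select_validation_candidates(truth, filt$dbs, updates,
                                 top_n_genes = cfg$top_n_genes))

  structure(
    list(filter_logs = c(filt$logs, list(reference = filt$reference_log)),
         recurrent_loci = filt$recurrent_loci,
         truth = truth,
         replicate_concordance = replicate_concordance,
         db_concordance = db_concordance,
         error_reports = rates,
         venn_counts = if (!is.null(venn)) venn_counts(venn) else NULL,
         evolution_summary = evo,
         gene_profiles = profiles,
         stratified = strat,
         candidates = candidates),
    class = "fnscope_study_report"
  )
}

try_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)

report_numbers <- function(report) {
  er <- lapply(report$error_reports, function(x)
    x[c("db_label", "n_db", "n_truth", "n_confirmed", "n_db_only",
        "n_rescued", "p_tp_pct", "p_fp_pct", "adjusted_p_fp_pct",
        "identification_pct", "p_fn_pct")])
  strat <- if (is.null(report$stratified)) NULL else
    lapply(report$stratified, function(s) list(
      cpg_odds_ratio = unname(s$cpg$odds_ratio),
      cpg_p_value = unname(s$cpg$p_value),
      cpg_test = s$cpg$test_used,
      fn_cpg_pct = unname(s$cpg$fn_cpg_pct),
      group_odds_ratio = unname(s$gene_group$odds_ratio),
      group_p_value = unname(s$gene_group$p_value),
      group_test = s$gene_group$test_used))
  list(
    filter_logs = lapply(report$filter_logs, as.data.frame),
    recurrent_loci = report$recurrent_loci,
    n_truth = callset_size(report$truth$truth_calls),
    replicate_summary = as.data.frame(report$replicate_concordance$summary),
    replicate_binned_either =
      as.data.frame(report$replicate_concordance$binned_either),
    replicate_binned_lowest =
      as.data.frame(report$replicate_concordance$binned_lowest),
    regression_hmaf =
      if (is.null(report$replicate_concordance$regression_hmaf)) NULL
      else as.data.frame(report$replicate_concordance$regression_hmaf),
    regression_low =
      if (is.null(report$replicate_concordance$regression_low)) NULL
      else as.data.frame(report$replicate_concordance$regression_low),
    db_concordance = if (is.null(report$db_concordance)) NULL
                     else as.data.frame(report$db_concordance),
    error_reports = er,
    venn_counts = as.list(report$venn_counts),
    evolution_summary = if (is.null(report$evolution_summary)) NULL
                        else as.data.frame(report$evolution_summary),
    gene_profiles = as.data.frame(report$gene_profiles),
    stratified = strat,
    n_candidates = length(report$candidates$candidates)
  )
}

#' Render a study report
#'
#' Writes the report as machine-readable JSON, a human-readable markdown
#' summary, or a bundle of TSV tables. All formats contain the same numbers;
#' undefined rates are rendered as `NA`, never as 0.
#'
#' @param report a [run_pipeline()] result.
#' @param format `"json"`, `"markdown"` or `"tsv-bundle"`.
#' @param out_dir output directory (created if needed).
#' @return character vector of paths written.
#' @export
render_report <- function(report, format = c("json", "markdown", "tsv-bundle"),
                          out_dir = ".") {
  stopifnot(inherits(report, "fnscope_study_report"))
  if (!is.character(format) ||
      !(format[1] %in% c("json", "markdown", "tsv-bundle"))) {
    abort(paste0("unknown report format '", format[1],
                 "'; use json, markdown or tsv-bundle"),
          class = "fnscope_config_error")
  }
  format <- format[1]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nums <- report_numbers(report)
  if (format == "json") {
    path <- file.path(out_dir, "study_report.json")
    jsonlite::write_json(nums, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (format == "markdown") {
    path <- file.path(out_dir, "study_report.md")
    lines <- c("# Study report", "", "## Error rates", "")
    for (er in nums$error_reports) {
      lines <- c(lines, sprintf(
        paste0("- %s: P-TP %s%% (%d/%d), P-FP %s%% (%d/%d), adjusted P-FP ",
               "%s%% (%d/%d), identification %s%% (%d/%d), P-FN %s%%"),
        er$db_label, fmt_na(er$p_tp_pct), er$n_confirmed, er$n_db,
        fmt_na(er$p_fp_pct), er$n_db_only, er$n_db,
        fmt_na(er$adjusted_p_fp_pct), er$n_db_only - er$n_rescued, er$n_db,
        fmt_na(er$identification_pct), er$n_confirmed, er$n_truth,
        fmt_na(er$p_fn_pct)))
    }
    lines <- c(lines, "", "## Replicate concordance", "",
               sprintf("- consistency %s%% (%d/%d)",
                       fmt_na(nums$replicate_summary$consistency_pct),
                       nums$replicate_summary$n_shared,
                       nums$replicate_summary$n_union),
               "", "## Truth set", "",
               sprintf("- %d truth calls", nums$n_truth),
               sprintf("- %d validation candidates", nums$n_candidates))
    writeLines(lines, path)
    return(invisible(path))
  }
  # tsv-bundle
  paths <- character(0)
  write_tbl <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tibble::as_tibble(df), p, progress = FALSE, na = "NA")
    paths <<- c(paths, p)
  }
  write_tbl(nums$replicate_summary, "replicate_summary")
  write_tbl(nums$replicate_binned_either, "replicate_binned_either")
  write_tbl(nums$replicate_binned_lowest, "replicate_binned_lowest")
  if (!is.null(nums$db_concordance)) write_tbl(nums$db_concordance,
                                               "db_concordance")
  er_tbl <- dplyr::bind_rows(lapply(nums$error_reports, tibble::as_tibble))
  write_tbl(er_tbl, "error_reports")
  write_tbl(nums$gene_profiles, "gene_profiles")
  invisible(paths)
}

fmt_na <- function(x) ifelse(is.na(x), "NA", format(x))
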