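#' Variant-call data model and MAF-dialect I/O
#'
#' A *variant call* is one observed mutation in one sample. Calls are held in
#' plain tibbles with a fixed set of columns; a [callset()] wraps such a tibble
#' together with a source label and a key scheme, and collapses duplicate keys.
#'
#' Canonical columns: `sample_id`, `gene`, `chrom`, `pos` (1-based),
#' `ref_allele`, `alt_allele` (`"-"` marks a pure insertion/deletion side),
#' `variant_class`, `protein_change`, `alt_count`, `ref_count`,
#' `population_af`, `in_cpg_island`, plus derived `depth` and `maf`.
#' `maf` is always recomputed from read counts when counts are present; a
#' pre-supplied allele-frequency value is used only when counts are absent.
#'
#' @name callset_io
NULL

CALL_COLUMNS <- c(
  "sample_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
  "variant_class", "protein_change", "alt_count", "ref_count",
  "population_af", "in_cpg_island"
)

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix and uppercases the sex/mitochondrial
#' chromosome names (`x -> X`, `y -> Y`, `mt`/`m -> MT`). Database exports
#' disagree on these dialects; all comparisons in the package run on the
#' normalized form.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr7", "chrX", "mt", "12"))
normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  low <- tolower(chrom)
  chrom[low == "x"] <- "X"
  chrom[low == "y"] <- "Y"
  chrom[low %in% c("m", "mt")] <- "MT"
  chrom
}

#' Build a normalized call table
#'
#' Coerces a data frame to the canonical call columns, fills optional columns
#' with missing values, normalizes chromosomes, and computes `depth` and
#' `maf`. Rows where both alleles are `"-"` or `pos < 1` are rejected.
#'
#' @param df data frame with at least `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `variant_class`.
#' @param maf optional numeric vector of pre-supplied allele frequencies, used
#'   only for rows without read counts.
#' @return tibble of canonical calls with `depth` and `maf`.
#' @export
variant_calls <- function(df, maf = NULL) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "gene", "chrom", "pos",
                "ref_allele", "alt_allele", "variant_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fnscope_config_error")
  }
  n <- nrow(df)
  out <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    gene = as.character(df$gene),
    chrom = normalize_chrom(df$chrom),
    pos = as.integer(df$pos),
    ref_allele = as.character(df$ref_allele),
    alt_allele = as.character(df$alt_allele),
    variant_class = as.character(df$variant_class),
    protein_change = if ("protein_change" %in% names(df)) {
      pc <- as.character(df$protein_change)
      pc[is.na(pc)] <- ""
      pc
    } else rep("", n),
    alt_count = if ("alt_count" %in% names(df)) as.integer(df$alt_count)
                else rep(NA_integer_, n),
    ref_count = if ("ref_count" %in% names(df)) as.integer(df$ref_count)
                else rep(NA_integer_, n),
    population_af = if ("population_af" %in% names(df)) as.numeric(df$population_af)
                    else rep(NA_real_, n),
    in_cpg_island = if ("in_cpg_island" %in% names(df)) as.logical(df$in_cpg_island)
                    else rep(NA, n)
  )
  if (any(!is.na(out$pos) & out$pos < 1)) {
    abort("pos must be >= 1", class = "fnscope_input_error")
  }
  if (any(out$ref_allele == "-" & out$alt_allele == "-")) {
    abort("ref_allele and alt_allele cannot both be '-'",
          class = "fnscope_input_error")
  }
  bad_counts <- (!is.na(out$alt_count) & out$alt_count < 0) |
                (!is.na(out$ref_count) & out$ref_count < 0)
  if (any(bad_counts)) {
    abort("read counts must be >= 0", class = "fnscope_input_error")
  }
  out$depth <- out$alt_count + out$ref_count
  out$maf <- ifelse(!is.na(out$depth) & out$depth > 0,
                    out$alt_count / out$depth, NA_real_)
  if (!is.null(maf)) {
    use_supplied <- is.na(out$maf) & !is.na(maf)
    out$maf[use_supplied] <- as.numeric(maf)[use_supplied]
  }
  out
}

#' Construct a callset
#'
#' Wraps a call table with a source label and comparison-key scheme.
#' Duplicate keys within the set are collapsed to the single record with the
#' greatest sequencing depth (first occurrence on ties or all-missing depth),
#' so `callset_size()` counts distinct keys.
#'
#' @param calls data frame of calls (passed through [variant_calls()]).
#' @param source_label label for the source, e.g. `"TarSeq1"` or `"GDSC"`.
#' @param key_scheme `"genomic"` (sample, chrom, pos, ref, alt) or
#'   `"protein"` (sample, gene, protein change).
#' @param maf optional pre-supplied allele frequencies (see [variant_calls()]).
#' @return object of class `fnscope_callset`.
#' @export
#' @examples
#' cs <- callset(
#'   data.frame(sample_id = "S1", gene = "TP53", chrom = "17", pos = 7578406,
#'              ref_allele = "C", alt_allele = "T",
#'              variant_class = "Missense", alt_count = 40L, ref_count = 60L),
#'   source_label = "demo")
#' callset_size(cs)
callset <- function(calls, source_label, key_scheme = c("genomic", "protein"),
                    maf = NULL) {
  key_scheme <- match.arg(key_scheme)
  calls <- variant_calls(calls, maf = maf)
  if (nrow(calls) > 0) {
    key <- make_key(calls, key_scheme)
    if (anyDuplicated(key)) {
      depth_rank <- ifelse(is.na(calls$depth), -1, calls$depth)
      ord <- order(key, -depth_rank)
      calls <- calls[ord[!duplicated(key[ord])], , drop = FALSE]
      # restore input ordering among survivors
      calls <- calls[order(match(make_key(calls, key_scheme),
                                 unique(key))), , drop = FALSE]
    }
  }
  structure(
    list(source_label = as.character(source_label),
         calls = calls, key_scheme = key_scheme),
    class = "fnscope_callset"
  )
}

#' @export
print.fnscope_callset <- function(x, ...) {
  cat(sprintf("<fnscope_callset> %s: %d calls (%s keys)\n",
              x$source_label, nrow(x$calls), x$key_scheme))
  print(utils::head(x$calls, 5))
  invisible(x)
}

#' @rdname callset
#' @param x a `fnscope_callset`.
#' @export
callset_size <- function(x) {
  stopifnot(inherits(x, "fnscope_callset"))
  nrow(x$calls)
}

#' @rdname callset
#' @export
is_callset <- function(x) inherits(x, "fnscope_callset")

#' Comparison keys for calls
#'
#' Builds the per-sample comparison key for each call. The genomic scheme
#' keys on (sample, chromosome, position, ref, alt) and ignores annotation;
#' the protein scheme keys on (sample, gene, protein change) and requires a
#' non-empty protein change. `make_key` is a pure function of its inputs.
#'
#' @param calls a call tibble or a `fnscope_callset`.
#' @param scheme `"genomic"` or `"protein"`; defaults to the callset's scheme.
#' @return character vector of keys, one per call.
#' @export
make_key <- function(calls, scheme = NULL) {
  if (is_callset(calls)) {
    if (is.null(scheme)) scheme <- calls$key_scheme
    calls <- calls$calls
  }
  scheme <- match.arg(scheme, c("genomic", "protein"))
  if (nrow(calls) == 0) return(character(0))
  if (scheme == "genomic") {
    paste(calls$sample_id, calls$chrom, calls$pos,
          calls$ref_allele, calls$alt_allele, sep = "|")
  } else {
    bad <- is.na(calls$protein_change) | calls$protein_change == "" |
           is.na(calls$gene) | calls$gene == ""
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "protein key scheme requires gene and protein_change (call %d: %s %s:%s)",
        i, calls$sample_id[i], calls$chrom[i], calls$pos[i]),
        class = "fnscope_key_error")
    }
    paste(calls$sample_id, calls$gene, calls$protein_change, sep = "|")
  }
}

#' Sample-agnostic locus keys
#'
#' Like [make_key()] but without the sample component; used for blacklists and
#' recurrent-germline flagging, which act on loci across all samples.
#'
#' @inheritParams make_key
#' @return character vector of locus keys.
#' @export
make_locus_key <- function(calls, scheme = NULL) {
  if (is_callset(calls)) {
    if (is.null(scheme)) scheme <- calls$key_scheme
    calls <- calls$calls
  }
  scheme <- match.arg(scheme, c("genomic", "protein"))
  if (nrow(calls) == 0) return(character(0))
  if (scheme == "genomic") {
    paste(calls$chrom, calls$pos, calls$ref_allele, calls$alt_allele, sep = "|")
  } else {
    paste(calls$gene, calls$protein_change, sep = "|")
  }
}

# Standard MAF column names -> canonical names. A user column_map can override
# any entry (canonical name -> column name in the file).
MAF_DEFAULT_COLUMNS <- c(
  sample_id = "Tumor_Sample_Barcode",
  gene = "Hugo_Symbol",
  chrom = "Chromosome",
  pos = "Start_position",
  ref_allele = "Reference_Allele",
  alt_allele = "Tumor_Seq_Allele2",
  variant_class = "Variant_Classification",
  protein_change = "Protein_Change",
  alt_count = "t_alt_count",
  ref_count = "t_ref_count",
  population_af = "population_af",
  maf = "i_tumor_vaf"
)

MAF_REQUIRED <- c("sample_id", "gene", "chrom", "pos",
                  "ref_allele", "alt_allele", "variant_class")

# Map common long-form MAF Variant_Classification values onto the canonical
# vocabulary; unknown values become "Other".
normalize_variant_class <- function(x) {
  x <- as.character(x)
  map <- c(
    Missense_Mutation = "Missense", Missense = "Missense",
    Nonsense_Mutation = "Nonsense", Nonsense = "Nonsense",
    Silent = "Silent",
    Splice_Site = "Splice_Site",
    Frame_Shift_Ins = "Frame_Shift_Ins", Frame_Shift_Del = "Frame_Shift_Del",
    In_Frame_Ins = "In_Frame_Ins", In_Frame_Del = "In_Frame_Del",
    Intron = "Intron",
    IGR = "Intergenic", Intergenic = "Intergenic"
  )
  out <- unname(map[x])
  out[is.na(out)] <- "Other"
  out
}

#' Read a MAF-dialect mutation table
#'
#' Reads a tab-separated mutation table (Mutation Annotation Format dialect)
#' into a [callset()]. Comment lines beginning with `#` are skipped,
#' chromosome labels are normalized, long-form variant classifications are
#' mapped onto the canonical vocabulary, and duplicate keys are collapsed
#' keeping the deepest record.
#'
#' @param path path to a tab-separated file with a header row.
#' @param source_label label for the resulting callset.
#' @param column_map optional named character vector mapping canonical names
#'   (`sample_id`, `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `variant_class`, `protein_change`, `alt_count`, `ref_count`,
#'   `population_af`, `maf`) to the column names used in the file.
#' @param key_scheme key scheme for the callset.
#' @return a `fnscope_callset`.
#' @export
read_maf <- function(path, source_label, column_map = NULL,
                     key_scheme = c("genomic", "protein")) {
  key_scheme <- match.arg(key_scheme)
  cols <- MAF_DEFAULT_COLUMNS
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad) > 0) {
      abort(paste0("unknown column_map entries: ", paste(bad, collapse = ", ")),
            class = "fnscope_config_error")
    }
    cols[names(column_map)] <- column_map
  }
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  # tolerate the other common spelling of the position column
  if (!(cols[["pos"]] %in% names(raw)) && "Start_Position" %in% names(raw) &&
      cols[["pos"]] == "Start_position") {
    cols[["pos"]] <- "Start_Position"
  }
  missing_req <- MAF_REQUIRED[!(cols[MAF_REQUIRED] %in% names(raw))]
  if (length(missing_req) > 0) {
    abort(paste0("MAF file ", path, " is missing required column(s): ",
                 paste(cols[missing_req], collapse = ", ")),
          class = "fnscope_config_error")
  }
  get_col <- function(name) {
    cn <- cols[[name]]
    if (cn %in% names(raw)) raw[[cn]] else NULL
  }
  parse_num <- function(x, what) {
    if (is.null(x)) return(NULL)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("unparseable %s at data line %d of %s: '%s'",
                    what, bad[1], path, x[bad[1]]),
            class = "fnscope_input_error")
    }
    out
  }
  df <- tibble::tibble(
    sample_id = get_col("sample_id"),
    gene = get_col("gene"),
    chrom = get_col("chrom"),
    pos = parse_num(get_col("pos"), "position"),
    ref_allele = get_col("ref_allele"),
    alt_allele = get_col("alt_allele"),
    variant_class = normalize_variant_class(get_col("variant_class"))
  )
  if (any(is.na(df$pos))) {
    abort(sprintf("unparseable position at data line %d of %s",
                  which(is.na(df$pos))[1], path),
          class = "fnscope_input_error")
  }
  pc <- get_col("protein_change")
  if (!is.null(pc)) df$protein_change <- pc
  ac <- parse_num(get_col("alt_count"), "alt read count")
  rc <- parse_num(get_col("ref_count"), "ref read count")
  if (!is.null(ac)) df$alt_count <- as.integer(round(ac))
  if (!is.null(rc)) df$ref_count <- as.integer(round(rc))
  paf <- parse_num(get_col("population_af"), "population allele frequency")
  if (!is.null(paf)) df$population_af <- paf
  if ("in_cpg_island" %in% names(raw)) {
    df$in_cpg_island <- as.logical(raw$in_cpg_island)
  }
  supplied_maf <- parse_num(get_col("maf"), "allele frequency")
  callset(df, source_label = source_label, key_scheme = key_scheme,
          maf = supplied_maf)
}

#' Write a callset as a MAF-dialect table
#'
#' Writes a tab-separated table using standard MAF column names, such that
#' [read_maf()] on the output reproduces the callset's keys, classifications
#' and allele frequencies. A `maf` column is written so that calls without
#' read counts round-trip their frequency.
#'
#' @param calls a `fnscope_callset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is_callset(calls))
  df <- calls$calls
  out <- tibble::tibble(
    Hugo_Symbol = df$gene,
    Chromosome = df$chrom,
    Start_position = df$pos,
    Reference_Allele = df$ref_allele,
    Tumor_Seq_Allele2 = df$alt_allele,
    Variant_Classification = df$variant_class,
    Tumor_Sample_Barcode = df$sample_id,
    Protein_Change = df$protein_change,
    t_alt_count = df$alt_count,
    t_ref_count = df$ref_count,
    population_af = df$population_af,
    i_tumor_vaf = df$maf,
    in_cpg_island = df$in_cpg_island
  )
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) abort(paste0("cannot write ", path, ": ",
                                     conditionMessage(e)),
                              class = "fnscope_io_error")
  )
  invisible(path)
}
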