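#' Callset concordance
#'
#' Set algebra between callsets under a common comparison key: pairwise
#' shared/exclusive partitions, consistency rates (intersection over union),
#' replicate consistency binned by mutant allele frequency, allele-frequency
#' agreement regression between technical replicates, and three-way
#' comparisons with the region fractions used to weigh genetic-evolution
#' explanations of database discordance.
#'
#' @name concordance
NULL

check_same_scheme <- function(a, b) {
  if (a$key_scheme != b$key_scheme) {
    abort(sprintf("key schemes differ: %s (%s) vs %s (%s)",
                  a$source_label, a$key_scheme, b$source_label, b$key_scheme),
          class = "fnscope_config_error")
  }
}

#' Compare two callsets by key
#'
#' @param a,b `fnscope_callset`s with the same key scheme.
#' @return a `fnscope_comparison`: list with key sets `shared`, `only_a`,
#'   `only_b` and the two source labels.
#' @export
compare_callsets <- function(a, b) {
  stopifnot(is_callset(a), is_callset(b))
  check_same_scheme(a, b)
  ka <- make_key(a)
  kb <- make_key(b)
  structure(
    list(shared = intersect(ka, kb),
         only_a = setdiff(ka, kb),
         only_b = setdiff(kb, ka),
         labels = c(a = a$source_label, b = b$source_label)),
    class = "fnscope_comparison"
  )
}

#' Consistency and inconsistency rates for a pairwise comparison
#'
#' The consistency rate is the number of shared calls divided by the size of
#' the union; the inconsistency rate is the number of source-exclusive calls
#' divided by the union. The two always sum to 1.
#'
#' @param cmp a [compare_callsets()] result.
#' @return tibble with counts, rates, and rates as percent (half-up, one
#'   decimal, the convention used when quoting such ratios).
#' @export
summarize_concordance <- function(cmp) {
  stopifnot(inherits(cmp, "fnscope_comparison"))
  n_shared <- length(cmp$shared)
  n_only_a <- length(cmp$only_a)
  n_only_b <- length(cmp$only_b)
  n_union <- n_shared + n_only_a + n_only_b
  if (n_union == 0) {
    abort("both callsets are empty: consistency rate undefined",
          class = "fnscope_undefined_rate_error")
  }
  consistency <- n_shared / n_union
  tibble::tibble(
    label_a = cmp$labels[["a"]], label_b = cmp$labels[["b"]],
    n_shared = n_shared, n_only_a = n_only_a, n_only_b = n_only_b,
    n_union = n_union,
    consistency_rate = consistency,
    inconsistency_rate = 1 - consistency,
    consistency_pct = percent1(consistency),
    inconsistency_pct = percent1(1 - consistency)
  )
}

# half-up rounding of a fraction to one decimal, in percent
percent1 <- function(x) floor(x * 1000 + 0.5) / 10

#' Replicate consistency binned by mutant allele frequency
#'
#' Partitions the union of two callsets into mutant-allele-frequency bins and
#' reports the per-bin consistency rate `shared / (shared + only_a + only_b)`.
#' Bins are half-open `[lo, hi)` with the final bin closed at 1.
#'
#' Two binning modes are reported by the package:
#' \describe{
#'   \item{`either`}{a call is binned by the maximum frequency observed in
#'     the two sources (a call passing the bin's cutoff in *either* replicate
#'     counts there); one-source calls use their own frequency.}
#'   \item{`lowest`}{a call is binned by the minimum frequency across the
#'     sources where it appears, i.e. the bin it would fall in when the lowest
#'     observed value is used as the cutoff.}
#' }
#'
#' @param a,b `fnscope_callset`s whose calls carry defined `maf`.
#' @param edges interior bin edges, strictly increasing fractions in (0, 1);
#'   default `c(0.01, 0.02, 0.05, 0.10)`.
#' @param mode `"either"` or `"lowest"`.
#' @return tibble with one row per bin: `bin`, `lo`, `hi`, `n_shared`,
#'   `n_only_a`, `n_only_b`, `n_total`, `rate`, `pct`.
#' @export
binned_consistency <- function(a, b, edges = c(0.01, 0.02, 0.05, 0.10),
                               mode = c("either", "lowest")) {
  mode <- match.arg(mode)
  stopifnot(is_callset(a), is_callset(b))
  check_same_scheme(a, b)
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0) || any(edges >= 1)) {
    abort("edges must be strictly increasing fractions in (0, 1)",
          class = "fnscope_config_error")
  }
  maf_a <- setNames(a$calls$maf, make_key(a))
  maf_b <- setNames(b$calls$maf, make_key(b))
  if (anyNA(maf_a) || anyNA(maf_b)) {
    abort("all calls must carry a defined maf for binning",
          class = "fnscope_input_error")
  }
  keys <- union(names(maf_a), names(maf_b))
  va <- maf_a[keys]
  vb <- maf_b[keys]
  pick <- if (mode == "either") pmax else pmin
  val <- ifelse(is.na(va), vb, ifelse(is.na(vb), va, pick(va, vb)))
  status <- ifelse(!is.na(va) & !is.na(vb), "shared",
                   ifelse(!is.na(va), "only_a", "only_b"))
  breaks <- c(0, edges, 1 + 1e-9)  # final bin closed at 1
  bin_idx <- cut(val, breaks = breaks, right = FALSE, include.lowest = TRUE,
                 labels = FALSE)
  lo <- c(0, edges)
  hi <- c(edges, 1)
  nb <- length(lo)
  out <- tibble::tibble(
    bin = sprintf("[%s,%s%s", format(lo), format(hi),
                  c(rep(")", length(edges)), "]")),
    lo = lo, hi = hi,
    n_shared = as.integer(tabulate(bin_idx[status == "shared"], nbins = nb)),
    n_only_a = as.integer(tabulate(bin_idx[status == "only_a"], nbins = nb)),
    n_only_b = as.integer(tabulate(bin_idx[status == "only_b"], nbins = nb))
  )
  out$n_total <- out$n_shared + out$n_only_a + out$n_only_b
  out$rate <- ifelse(out$n_total > 0, out$n_shared / out$n_total, NA_real_)
  out$pct <- percent1(out$rate)
  out
}

#' Allele-frequency agreement between replicates
#'
#' Ordinary least-squares regression of the second source's mutant allele
#' frequency on the first, over shared calls only (a scatter needs two
#' coordinates). Pairs where either side has sequencing depth below
#' `min_depth` are excluded. `restrict = "hmAF"` keeps pairs with both
#' frequencies at or above `maf_cutoff`; `restrict = "low"` keeps pairs where
#' at least one side is below it.
#'
#' @param a,b `fnscope_callset`s.
#' @param restrict `"hmAF"` or `"low"`.
#' @param maf_cutoff high-frequency cutoff (default 0.10).
#' @param min_depth minimum read depth on both sides (default 20).
#' @return tibble with `n`, `slope`, `intercept`, `r`, `r_squared`.
#' @export
maf_regression <- function(a, b, restrict = c("hmAF", "low"),
                           maf_cutoff = 0.10, min_depth = 20L) {
  restrict <- match.arg(restrict)
  stopifnot(is_callset(a), is_callset(b))
  check_same_scheme(a, b)
  ka <- make_key(a); kb <- make_key(b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  x <- a$calls$maf[ia]; y <- b$calls$maf[ib]
  da <- a$calls$depth[ia]; db <- b$calls$depth[ib]
  ok <- !is.na(x) & !is.na(y) &
        !is.na(da) & !is.na(db) & da >= min_depth & db >= min_depth
  keep <- if (restrict == "hmAF") x >= maf_cutoff & y >= maf_cutoff
          else x < maf_cutoff | y < maf_cutoff
  x <- x[ok & keep]; y <- y[ok & keep]
  if (length(x) < 3) {
    abort(sprintf("only %d usable pairs; at least 3 needed", length(x)),
          class = "fnscope_insufficient_data_error")
  }
  fit <- lm(y ~ x)
  r <- stats::cor(x, y)
  tibble::tibble(
    restrict = restrict, n = length(x),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = r, r_squared = r^2
  )
}

#' Three-way callset comparison
#'
#' Partitions the union of three callsets into the seven exclusive regions.
#'
#' @param a,b,c `fnscope_callset`s with the same key scheme.
#' @return a `fnscope_venn`: named list of the 7 region key sets
#'   (`a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`) plus `labels`.
#' @export
three_way_venn <- function(a, b, c) {
  stopifnot(is_callset(a), is_callset(b), is_callset(c))
  check_same_scheme(a, b); check_same_scheme(a, c)
  ka <- make_key(a); kb <- make_key(b); kc <- make_key(c)
  keys <- unique(c(ka, kb, kc))
  ina <- keys %in% ka; inb <- keys %in% kb; inc <- keys %in% kc
  structure(
    list(a_only = keys[ina & !inb & !inc],
         b_only = keys[!ina & inb & !inc],
         c_only = keys[!ina & !inb & inc],
         ab = keys[ina & inb & !inc],
         ac = keys[ina & !inb & inc],
         bc = keys[!ina & inb & inc],
         abc = keys[ina & inb & inc],
         labels = c(a = a$source_label, b = b$source_label,
                    c = c$source_label)),
    class = "fnscope_venn"
  )
}

#' @rdname three_way_venn
#' @param venn a `fnscope_venn`.
#' @return `venn_counts()`: named integer vector of the 7 region sizes.
#' @export
venn_counts <- function(venn) {
  stopifnot(inherits(venn, "fnscope_venn"))
  vapply(venn[c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc")],
         length, integer(1))
}

#' Reference coverage of database-exclusive calls
#'
#' If cell-line evolution (rather than sequencing error) explained why two
#' databases disagree, calls specific to one database would be absent from an
#' independent deep-sequencing reference, and the reference would mainly add
#' calls of its own. This summary quantifies those regions: for each database
#' role, the fraction of its calls absent from the other database that the
#' reference nevertheless detects; the same fraction over all pairwise
#' inconsistent calls; and the number of reference-only calls.
#'
#' @param venn a [three_way_venn()] result.
#' @param roles named character vector mapping each of `reference`, `db1`,
#'   `db2` to one of the venn's source labels.
#' @return tibble with counts and fractions (and percent, half-up one
#'   decimal) for the four summaries.
#' @export
evolution_model_test <- function(venn, roles) {
  stopifnot(inherits(venn, "fnscope_venn"))
  need <- c("reference", "db1", "db2")
  if (!all(need %in% names(roles))) {
    abort("roles must name reference, db1 and db2",
          class = "fnscope_config_error")
  }
  slot <- vapply(roles[need], function(lab) {
    i <- which(venn$labels == lab)
    if (length(i) != 1) {
      abort(sprintf("role label '%s' not among venn labels", lab),
            class = "fnscope_config_error")
    }
    names(venn$labels)[i]
  }, character(1))
  names(slot) <- need
  region <- function(in_a, in_b, in_c) {
    nm <- c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc")
    want <- c(in_a & !in_b & !in_c, !in_a & in_b & !in_c, !in_a & !in_b & in_c,
              in_a & in_b & !in_c, in_a & !in_b & in_c, !in_a & in_b & in_c,
              in_a & in_b & in_c)
    length(venn[[nm[which(want)]]])
  }
  memb <- function(role) slot[[role]]
  inr <- function(role, x) switch(memb(role), a = x[1], b = x[2], c = x[3])
  # count keys by (db1, db2, ref) membership
  cnt <- function(d1, d2, rf) {
    x <- logical(3)
    x[match(memb("db1"), c("a", "b", "c"))] <- d1
    x[match(memb("db2"), c("a", "b", "c"))] <- d2
    x[match(memb("reference"), c("a", "b", "c"))] <- rf
    region(x[1], x[2], x[3])
  }
  db1_not_db2 <- cnt(TRUE, FALSE, TRUE) + cnt(TRUE, FALSE, FALSE)
  db1_not_db2_in_ref <- cnt(TRUE, FALSE, TRUE)
  db2_not_db1 <- cnt(FALSE, TRUE, TRUE) + cnt(FALSE, TRUE, FALSE)
  db2_not_db1_in_ref <- cnt(FALSE, TRUE, TRUE)
  incons <- db1_not_db2 + db2_not_db1
  incons_in_ref <- db1_not_db2_in_ref + db2_not_db1_in_ref
  ref_only <- cnt(FALSE, FALSE, TRUE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    quantity = c("db1_exclusive_in_reference", "db2_exclusive_in_reference",
                 "pairwise_inconsistent_in_reference", "reference_only"),
    numerator = c(db1_not_db2_in_ref, db2_not_db1_in_ref, incons_in_ref,
                  ref_only),
    denominator = c(db1_not_db2, db2_not_db1, incons, NA_integer_),
    fraction = c(frac(db1_not_db2_in_ref, db1_not_db2),
                 frac(db2_not_db1_in_ref, db2_not_db1),
                 frac(incons_in_ref, incons), NA_real_),
    pct = percent1(c(frac(db1_not_db2_in_ref, db1_not_db2),
                     frac(db2_not_db1_in_ref, db2_not_db1),
                     frac(incons_in_ref, incons), NA_real_))
  )
}
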