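#' Stratified error statistics
#'
#' Association of false-negative status with CpG-island membership and with
#' per-gene false-negative groups (2x2 tests), and read-count comparisons
#' between groups (Mann-Whitney rank test, Mood's median test). Test
#' selection for 2x2 tables is deterministic and always reported: Fisher's
#' exact test when any expected cell count is below 5, otherwise the Pearson
#' chi-square test.
#'
#' @name strat_stats
NULL

#' Read a BED3 interval file
#'
#' Reads the first three columns (chrom, start, end) of a BED file.
#' Coordinates are 0-based half-open per the UCSC convention; conversion to
#' the 1-based call coordinates happens inside [annotate_cpg()].
#'
#' @param path path to a BED file (track/browser/comment lines are skipped).
#' @return tibble with `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    abort("BED lines must have at least 3 tab-separated fields",
          class = "fnscope_input_error")
  }
  out <- tibble::tibble(
    chrom = normalize_chrom(vapply(parts, `[[`, character(1), 1)),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    end = as.integer(vapply(parts, `[[`, character(1), 3))
  )
  if (any(is.na(out$start) | is.na(out$end))) {
    abort("unparseable BED coordinates", class = "fnscope_input_error")
  }
  if (any(out$start >= out$end)) {
    abort("BED intervals must satisfy start < end",
          class = "fnscope_input_error")
  }
  out
}

#' Annotate calls with CpG-island membership
#'
#' Sets `in_cpg_island` to `TRUE` for calls whose 1-based position `p` falls
#' in a 0-based half-open island `(start, end]`, i.e. `start < p <= end` on
#' the same chromosome, and `FALSE` otherwise. Overlap is computed with
#' `GenomicRanges::findOverlaps`.
#'
#' @param calls a `fnscope_callset` with genomic positions.
#' @param islands a tibble as returned by [read_bed3()] (0-based half-open).
#' @return the callset with `in_cpg_island` filled in.
#' @export
annotate_cpg <- function(calls, islands) {
  stopifnot(is_callset(calls))
  if (any(islands$start >= islands$end)) {
    abort("islands must satisfy start < end", class = "fnscope_input_error")
  }
  df <- calls$calls
  if (nrow(df) == 0) return(calls)
  if (nrow(islands) == 0) {
    calls$calls$in_cpg_island <- FALSE
    return(calls)
  }
  call_gr <- GenomicRanges::GRanges(
    seqnames = df$chrom, ranges = IRanges::IRanges(start = df$pos, width = 1))
  isl_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(islands$chrom),
    ranges = IRanges::IRanges(start = islands$start + 1L, end = islands$end))
  hits <- GenomicRanges::findOverlaps(call_gr, isl_gr)
  flag <- logical(nrow(df))
  flag[unique(S4Vectors::queryHits(hits))] <- TRUE
  calls$calls$in_cpg_island <- flag
  calls
}

# Deterministic 2x2 test: Fisher's exact when any expected count < 5, else
# Pearson chi-square. The sample odds ratio is (a*d)/(b*c); with a zero cell
# it is reported as Inf/0/NaN by that formula, alongside a Haldane-Anscombe
# corrected value (+0.5 to each cell).
two_by_two_test <- function(tab, labels = dimnames(tab)) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  odds_ratio <- (a * d) / (b * c_)
  or_haldane <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  if (degenerate) {
    return(structure(list(table = tab, odds_ratio = odds_ratio,
                          odds_ratio_haldane = or_haldane,
                          p_value = NA_real_, test_used = "none",
                          degenerate = TRUE),
                     class = "fnscope_two_by_two"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    test_used <- "fisher"
    p <- fisher.test(tab)$p.value
  } else {
    test_used <- "chi_square"
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  structure(list(table = tab, odds_ratio = odds_ratio,
                 odds_ratio_haldane = or_haldane,
                 p_value = p, test_used = test_used, degenerate = FALSE),
            class = "fnscope_two_by_two")
}

#' @export
print.fnscope_two_by_two <- function(x, ...) {
  cat("<fnscope_two_by_two>\n")
  print(x$table)
  cat(sprintf("  OR %.4g (Haldane %.4g), p = %.4g [%s]%s\n",
              x$odds_ratio, x$odds_ratio_haldane, x$p_value, x$test_used,
              if (isTRUE(x$degenerate)) " DEGENERATE" else ""))
  invisible(x)
}

#' CpG-island association with false-negative status
#'
#' Cross-tabulates truth-set calls by CpG-island membership against whether
#' the database missed them (false negative) or confirmed them, and tests the
#' association. Also reports the CpG share of all false negatives,
#' `|CpG and FN| / |FN|`, which bounds how much of the false-negative burden
#' CpG regions can explain.
#'
#' @param truth a [build_truth_set()] result whose truth calls carry
#'   `in_cpg_island` flags (see [annotate_cpg()]).
#' @param report an [error_report()] for the database under test.
#' @return a `fnscope_two_by_two` with extra fields `fn_cpg_fraction` and
#'   `fn_cpg_pct`.
#' @export
cpg_fn_association <- function(truth, report) {
  stopifnot(inherits(truth, "fnscope_truth_set"),
            inherits(report, "fnscope_error_report"))
  tcalls <- truth$truth_calls$calls
  if (anyNA(tcalls$in_cpg_island)) {
    abort("truth calls lack in_cpg_island flags; run annotate_cpg() first",
          class = "fnscope_annotation_required_error")
  }
  is_fn <- make_key(truth$truth_calls) %in% report$fn_keys
  cpg <- tcalls$in_cpg_island
  tab <- matrix(c(sum(cpg & is_fn), sum(cpg & !is_fn),
                  sum(!cpg & is_fn), sum(!cpg & !is_fn)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("CpG", "non-CpG"), c("FN", "confirmed")))
  res <- two_by_two_test(tab)
  n_fn <- sum(is_fn)
  res$fn_cpg_fraction <- if (n_fn > 0) sum(cpg & is_fn) / n_fn else NA_real_
  res$fn_cpg_pct <- percent1(res$fn_cpg_fraction)
  res
}

#' Gene-group association with false-negative status
#'
#' Cross-tabulates truth-set calls in grouped genes (high vs low per-gene
#' false-negative group, see [gene_error_profiles()]) against
#' false-negative/confirmed status in `report`. The groups may come from one
#' database and the report from another: evaluating groups defined on one
#' platform against a second platform's misses tests whether gene-dependent
#' false negativity is platform-specific or shared.
#'
#' @param profiles a [gene_error_profiles()] tibble defining the groups.
#' @param truth a [build_truth_set()] result.
#' @param report an [error_report()].
#' @return a `fnscope_two_by_two` (rows high/low group, columns FN/confirmed).
#' @export
group_fn_association <- function(profiles, truth, report) {
  stopifnot(inherits(truth, "fnscope_truth_set"),
            inherits(report, "fnscope_error_report"))
  tcalls <- truth$truth_calls$calls
  grp <- setNames(profiles$group, profiles$gene)[tcalls$gene]
  keep <- !is.na(grp) & grp %in% c("high", "low")
  is_fn <- (make_key(truth$truth_calls) %in% report$fn_keys)[keep]
  grp <- grp[keep]
  tab <- matrix(c(sum(grp == "high" & is_fn), sum(grp == "high" & !is_fn),
                  sum(grp == "low" & is_fn), sum(grp == "low" & !is_fn)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("high", "low"), c("FN", "confirmed")))
  two_by_two_test(tab)
}

extract_counts <- function(x, count_field = c("alt", "depth")) {
  count_field <- match.arg(count_field)
  if (is_callset(x)) x <- x$calls
  if (is.data.frame(x)) {
    x <- if (count_field == "alt") x$alt_count else x$depth
  }
  out <- as.numeric(x)
  out[!is.na(out)]
}

# Exact two-sided rank-sum p-value with ties, by dynamic programming over the
# doubled midranks (counts of size-n_a subsets achieving each rank sum).
exact_ranksum_p <- function(xa, xb) {
  na <- length(xa); nb <- length(xb); n <- na + nb
  r2 <- as.integer(round(2 * rank(c(xa, xb))))
  s_obs <- sum(r2[seq_len(na)])
  maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  dp <- vector("list", na + 1)
  dp[[1]] <- c(1, numeric(maxsum))
  for (k in seq_len(na)) dp[[k + 1]] <- numeric(maxsum + 1)
  for (v in r2) {
    for (k in seq(na, 1)) {
      src <- dp[[k]]
      if (v < maxsum + 1) {
        dp[[k + 1]][(v + 1):(maxsum + 1)] <-
          dp[[k + 1]][(v + 1):(maxsum + 1)] + src[1:(maxsum + 1 - v)]
      }
    }
  }
  dist <- dp[[na + 1]]
  sums <- 0:maxsum
  mu <- na * (n + 1)  # doubled scale
  dev_obs <- abs(s_obs - mu)
  p <- sum(dist[abs(sums - mu) >= dev_obs - 1e-9]) / sum(dist)
  min(p, 1)
}

#' Mann-Whitney comparison of mutation read counts
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the
#' mutation-supporting read counts of two call groups. The U statistic counts
#' pairs where the first group's value exceeds the second's (ties count 1/2).
#' The exact tie-aware null distribution is enumerated by dynamic programming
#' when `n_a * n_b <= 1e4`; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param group_a,group_b `fnscope_callset`s, call tibbles, or numeric
#'   vectors of counts.
#' @param count_field `"alt"` (mutation-supporting reads, the default, per
#'   MAF `t_alt_count` semantics) or `"depth"` (total depth).
#' @return tibble with `n_a`, `n_b`, `u_statistic`, `p_value`, `method`.
#' @export
compare_read_counts <- function(group_a, group_b,
                                count_field = c("alt", "depth")) {
  xa <- extract_counts(group_a, count_field)
  xb <- extract_counts(group_b, count_field)
  na <- length(xa); nb <- length(xb)
  if (na == 0 || nb == 0) {
    abort("both groups must contain at least one count",
          class = "fnscope_insufficient_data_error")
  }
  r <- rank(c(xa, xb))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na * nb <= 1e4) {
    method <- "exact"
    p <- exact_ranksum_p(xa, xb)
  } else {
    method <- "normal_approx"
    n <- na + nb
    ties <- table(c(xa, xb))
    mu <- na * nb / 2
    sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5)
  }
  tibble::tibble(n_a = na, n_b = nb, u_statistic = u, p_value = p,
                 method = method)
}

#' Mood's median test on read counts
#'
#' Partitions the pooled counts at the pooled median, cross-tabulates group
#' against above-median vs at-or-below-median, and applies the 2x2 selection
#' rule (Fisher's exact / chi-square). When all values are equal the table is
#' degenerate and flagged rather than tested.
#'
#' @inheritParams compare_read_counts
#' @return a `fnscope_two_by_two` with extra field `pooled_median`.
#' @export
median_count_test <- function(group_a, group_b,
                              count_field = c("alt", "depth")) {
  xa <- extract_counts(group_a, count_field)
  xb <- extract_counts(group_b, count_field)
  if (length(xa) == 0 || length(xb) == 0) {
    abort("both groups must contain at least one count",
          class = "fnscope_insufficient_data_error")
  }
  m <- median(c(xa, xb))
  tab <- matrix(c(sum(xa > m), sum(xa <= m),
                  sum(xb > m), sum(xb <= m)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("group_a", "group_b"),
                                c("above_median", "at_or_below")))
  res <- two_by_two_test(tab)
  res$pooled_median <- m
  res
}
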