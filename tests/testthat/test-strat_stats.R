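test_that("CpG annotation respects the 0-based half-open boundary convention", {
  islands <- tibble::tibble(chrom = "1", start = c(99, 100, 0),
                            end = c(100, 200, 99))
  cs100 <- callset(mk_calls(1, pos = 100), "x")
  # (99,100] contains 100; (100,200] contains 100? no: start < p <= end
  one_island <- function(s, e) annotate_cpg(
    cs100, tibble::tibble(chrom = "1", start = s, end = e))$calls$in_cpg_island
  expect_true(one_island(99, 100))
  expect_true(one_island(100, 200) == FALSE)  # p = 100 not > start = 100
  expect_false(one_island(0, 99))
  expect_error(annotate_cpg(cs100, tibble::tibble(chrom = "1", start = 5,
                                                  end = 5)),
               class = "fnscope_input_error")
})

test_that("CpG annotation equals brute-force interval scan on random data", {
  set.seed(17)
  n <- 500
  cs <- callset(mk_calls(n, chrom = sample(c("1", "2", "X"), n, replace = TRUE),
                         pos = sample.int(5000, n, replace = TRUE),
                         sample_id = sample(c("S1", "S2"), n, replace = TRUE)),
                "x")
  st <- sample.int(4800, 20)
  islands <- tibble::tibble(chrom = sample(c("1", "2", "X"), 20, replace = TRUE),
                            start = st, end = st + sample.int(300, 20))
  got <- annotate_cpg(cs, islands)$calls
  for (i in seq_len(nrow(got))) {
    expected <- any(islands$chrom == got$chrom[i] &
                    islands$start < got$pos[i] & got$pos[i] <= islands$end)
    expect_identical(got$in_cpg_island[i], expected)
  }
})

test_that("BED reader validates coordinates and skips headers", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=cpg", "# comment",
               "chr1\t99\t200\tisland1", "2\t10\t20"), f)
  bed <- read_bed3(f)
  expect_equal(nrow(bed), 2)
  expect_equal(bed$chrom, c("1", "2"))
  f2 <- tempfile(fileext = ".bed")
  writeLines("1\t30\t20", f2)
  expect_error(read_bed3(f2), class = "fnscope_input_error")
})

test_that("2x2 test selection rule is deterministic and reported", {
  small <- matrix(c(2, 8, 3, 7), 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  res_small <- fnscope:::two_by_two_test(small)
  expect_equal(res_small$test_used, "fisher")
  expect_equal(res_small$p_value, fisher.test(small)$p.value)
  big <- matrix(c(30, 40, 50, 60), 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  res_big <- fnscope:::two_by_two_test(big)
  expect_equal(res_big$test_used, "chi_square")
  expect_equal(res_big$p_value,
               suppressWarnings(chisq.test(big, correct = FALSE)$p.value))
  expect_equal(res_big$odds_ratio, (30 * 60) / (40 * 50))
  degen <- matrix(c(5, 0, 7, 0), 2)
  expect_true(fnscope:::two_by_two_test(degen)$degenerate)
})

test_that("CpG-FN association reports composition and extreme odds", {
  # 625 truth calls: FN set of 318 with 50 CpG; confirmed 307 with 25 CpG
  cpg_flags <- c(rep(TRUE, 50), rep(FALSE, 268),    # FN calls
                 rep(TRUE, 25), rep(FALSE, 282))    # confirmed calls
  ref <- keyset_callset(1:625, "T", maf = 0.5, cpg = cpg_flags)
  ts <- build_truth_set(ref)
  db <- keyset_callset(319:625, "DB", maf = 0.5)
  rep_ <- error_report(db, ts)
  res <- cpg_fn_association(ts, rep_)
  expect_equal(unname(res$table["CpG", "FN"]), 50)
  expect_equal(res$fn_cpg_pct, 15.7)
  expect_equal(res$odds_ratio, (50 * 282) / (25 * 268))

  # all FN CpG, all confirmed non-CpG -> infinite OR, composition 100%
  ref2 <- keyset_callset(1:40, "T", maf = 0.5,
                         cpg = c(rep(TRUE, 20), rep(FALSE, 20)))
  ts2 <- build_truth_set(ref2)
  rep2 <- error_report(keyset_callset(21:40, "DB", maf = 0.5), ts2)
  res2 <- cpg_fn_association(ts2, rep2)
  expect_equal(res2$odds_ratio, Inf)
  expect_equal(res2$fn_cpg_fraction, 1)

  # missing flags are an annotation error
  ts3 <- build_truth_set(keyset_callset(1:10, "T", maf = 0.5, cpg = NA))
  rep3 <- error_report(keyset_callset(1:10, "DB", maf = 0.5), ts3)
  expect_error(cpg_fn_association(ts3, rep3),
               class = "fnscope_annotation_required_error")
})

test_that("gene-group association recovers a planted group effect", {
  set.seed(23)
  # 30 genes, 10 calls each; high-group genes missed at 0.7, low at 0.2
  genes <- sprintf("G%02d", 1:30)
  df <- mk_calls(300, gene = rep(genes, each = 10), pos = 1:300,
                 alt_count = 500L, ref_count = 500L)
  ts <- build_truth_set(callset(df, "T"))
  miss_p <- ifelse(rep(genes, each = 10) %in% genes[1:15], 0.7, 0.2)
  detected <- runif(300) > miss_p
  db <- callset(df[detected, ], "DB")
  rep_ <- error_report(db, ts)
  prof <- gene_error_profiles(ts, db)
  res <- group_fn_association(prof, ts, rep_)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.05)
  # degenerate single-group input is flagged, not mis-tested
  prof_low <- prof
  prof_low$group <- "low"
  res_deg <- group_fn_association(prof_low, ts, rep_)
  expect_true(res_deg$degenerate)
})

test_that("rank-sum test: exact enumeration, ties, and wilcox agreement", {
  # identical samples -> exact p of 1
  r_same <- compare_read_counts(c(3, 5, 9), c(3, 5, 9))
  expect_equal(r_same$method, "exact")
  expect_equal(r_same$p_value, 1.0)
  # complete separation of {1,2,3} vs {10,20,30}: U = 0, exact p = 0.1
  r_sep <- compare_read_counts(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r_sep$u_statistic, 0)
  expect_equal(r_sep$p_value, 0.1)
  # orientation: swapping groups mirrors U, same p
  r_swap <- compare_read_counts(c(10, 20, 30), c(1, 2, 3))
  expect_equal(r_swap$u_statistic, 9)
  expect_equal(r_swap$p_value, 0.1)
  # tie-free data: exact path matches wilcox.test's exact p
  set.seed(3)
  xa <- sample(1:1000, 12); xb <- sample(2000:3000, 15)
  ours <- compare_read_counts(xa, xb)
  ref <- wilcox.test(xa, xb, exact = TRUE)
  expect_equal(ours$u_statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # large groups: normal approximation matches wilcox.test with correction
  ya <- rpois(150, 40); yb <- rpois(130, 44)
  ours_big <- compare_read_counts(ya, yb)
  expect_equal(ours_big$method, "normal_approx")
  ref_big <- wilcox.test(ya, yb, exact = FALSE, correct = TRUE)
  expect_equal(ours_big$p_value, ref_big$p.value, tolerance = 1e-10)
  expect_error(compare_read_counts(numeric(0), 1:3),
               class = "fnscope_insufficient_data_error")
})

test_that("rank-sum test has power against a shifted negative binomial", {
  set.seed(29)
  rejections <- vapply(1:150, function(i) {
    a <- rnbinom(120, mu = 30, size = 5)
    b <- rnbinom(110, mu = 42, size = 5)
    compare_read_counts(a, b)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("median test partitions at the pooled median like the direct computation", {
  set.seed(37)
  a <- rpois(60, 30); b <- rpois(50, 33)
  res <- median_count_test(a, b)
  m <- median(c(a, b))
  expect_equal(unname(res$table["group_a", "above_median"]), sum(a > m))
  expect_equal(unname(res$table["group_b", "at_or_below"]), sum(b <= m))
  # identical groups: OR near 1 (Haldane-corrected to dodge zero cells)
  same <- median_count_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$odds_ratio_haldane, 1, tolerance = 0.5)
  # disjoint ranges: extreme odds ratio and small p
  far <- median_count_test(rpois(40, 5), rpois(40, 100))
  expect_true(far$odds_ratio < 0.05 || far$odds_ratio == 0)
  expect_lt(far$p_value, 1e-6)
  # all values equal: degenerate flag
  expect_true(median_count_test(rep(5, 10), rep(5, 12))$degenerate)
})
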