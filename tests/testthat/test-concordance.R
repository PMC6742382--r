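brute_force_partition <- function(ka, kb) {
  shared <- character(0); only_a <- character(0)
  for (k in ka) if (k %in% kb) shared <- c(shared, k) else only_a <- c(only_a, k)
  only_b <- character(0)
  for (k in kb) if (!(k %in% ka)) only_b <- c(only_b, k)
  list(shared = shared, only_a = only_a, only_b = only_b)
}

test_that("pairwise comparison partitions keys exactly", {
  a <- random_callset(60, "A", seed = 1)
  b <- random_callset(60, "B", seed = 2)
  cmp <- compare_callsets(a, b)
  bf <- brute_force_partition(make_key(a), make_key(b))
  expect_setequal(cmp$shared, bf$shared)
  expect_setequal(cmp$only_a, bf$only_a)
  expect_setequal(cmp$only_b, bf$only_b)
  # regions disjoint, union adds up
  expect_length(intersect(cmp$shared, cmp$only_a), 0)
  expect_length(intersect(cmp$shared, cmp$only_b), 0)
  expect_equal(length(cmp$shared) + length(cmp$only_a) + length(cmp$only_b),
               length(union(make_key(a), make_key(b))))
  # identical sets
  cmp2 <- compare_callsets(a, a)
  expect_length(cmp2$only_a, 0)
  expect_length(cmp2$only_b, 0)
  # mismatched schemes refuse to compare
  prot <- callset(mk_calls(2, protein_change = "p.X"), "P",
                  key_scheme = "protein")
  expect_error(compare_callsets(a, prot), class = "fnscope_config_error")
})

test_that("concordance summary rates are complementary and symmetric", {
  a <- random_callset(80, "A", seed = 5)
  b <- random_callset(80, "B", seed = 6)
  s_ab <- summarize_concordance(compare_callsets(a, b))
  s_ba <- summarize_concordance(compare_callsets(b, a))
  expect_equal(s_ab$consistency_rate + s_ab$inconsistency_rate, 1)
  expect_equal(s_ab$consistency_rate, s_ba$consistency_rate)
  # zero overlap
  a2 <- keyset_callset(1:5, "A")
  b2 <- keyset_callset(6:10, "B")
  expect_equal(summarize_concordance(compare_callsets(a2, b2))$consistency_rate, 0)
  # empty union is an error, not a zero
  e <- callset(mk_calls(0), "E")
  expect_error(summarize_concordance(compare_callsets(e, e)),
               class = "fnscope_undefined_rate_error")
})

test_that("binned consistency matches brute-force binning in both modes", {
  # 12-call fixture spanning all default bins, with shared calls whose two
  # mafs fall in different bins so the modes disagree
  mafs_a <- c(0.005, 0.012, 0.03, 0.07, 0.5, 0.015, 0.08, 0.3)
  a <- keyset_callset(1:8, "A", maf = mafs_a)
  mafs_b <- c(0.009, 0.045, 0.03, 0.12, 0.5, 0.55)
  b <- keyset_callset(c(1, 2, 3, 4, 5, 9), "B", maf = mafs_b)
  # extra b-only low-maf calls
  b2 <- combine_callsets(list(b, keyset_callset(10:13, "B", maf = 0.006)), "B")
  edges <- c(0.01, 0.02, 0.05, 0.10)
  for (mode in c("either", "lowest")) {
    tab <- binned_consistency(a, b2, edges, mode)
    # brute force
    ka <- make_key(a); kb <- make_key(b2)
    va <- setNames(a$calls$maf, ka); vb <- setNames(b2$calls$maf, kb)
    keys <- union(ka, kb)
    pick <- if (mode == "either") max else min
    bf <- sapply(keys, function(k) {
      vals <- c(va[k], vb[k]); vals <- vals[!is.na(vals)]
      pick(vals)
    })
    lo <- c(0, edges); hi <- c(edges, 1)
    for (i in seq_along(lo)) {
      in_bin <- bf >= lo[i] & (bf < hi[i] | (i == length(lo) & bf <= 1))
      ks <- keys[in_bin]
      expect_equal(tab$n_shared[i], sum(ks %in% ka & ks %in% kb))
      expect_equal(tab$n_total[i], length(ks))
    }
    # per-bin shared counts sum to |shared|
    expect_equal(sum(tab$n_shared), length(intersect(ka, kb)))
  }
  # all shared with both mafs >= 0.10 -> top-bin rate 1
  hi_cs <- keyset_callset(1:20, "H", maf = 0.4)
  tab_hi <- binned_consistency(hi_cs, hi_cs, edges, "either")
  expect_equal(tab_hi$rate[5], 1)
  expect_error(binned_consistency(a, b2, c(0.5, 0.2)),
               class = "fnscope_config_error")
})

test_that("maf regression recovers identity, rejects shuffled pairs", {
  set.seed(31)
  mafs <- runif(120, 0.12, 0.95)
  a <- keyset_callset(1:120, "A", maf = mafs)
  expect_equal(maf_regression(a, a, "hmAF")$r_squared, 1)

  # independent mafs: r^2 near zero
  b <- keyset_callset(1:500, "B", maf = runif(500, 0.12, 0.95))
  a2 <- keyset_callset(1:500, "A", maf = runif(500, 0.12, 0.95))
  expect_lt(maf_regression(a2, b, "hmAF")$r_squared, 0.05)

  # depth filter: pairs under min_depth are excluded from n
  shallow <- keyset_callset(1:10, "A", maf = 0.5, depth = 10)
  deep <- keyset_callset(11:30, "A", maf = mafs[1:20], depth = 1000)
  aa <- combine_callsets(list(shallow, deep), "A")
  r <- maf_regression(aa, aa, "hmAF", min_depth = 20)
  expect_equal(r$n, 20)
  expect_error(maf_regression(keyset_callset(1:2, "A"), keyset_callset(1:2, "B")),
               class = "fnscope_insufficient_data_error")
})

test_that("three-way venn regions are exact for identical, disjoint and random sets", {
  a <- keyset_callset(1:10, "A")
  v_same <- venn_counts(three_way_venn(a, a, a))
  expect_equal(unname(v_same["abc"]), 10)
  expect_equal(sum(v_same), 10)

  d1 <- keyset_callset(1:3, "A"); d2 <- keyset_callset(4:6, "B")
  d3 <- keyset_callset(7:9, "C")
  v_dis <- venn_counts(three_way_venn(d1, d2, d3))
  expect_equal(unname(v_dis[c("a_only", "b_only", "c_only")]), c(3, 3, 3))
  expect_equal(sum(v_dis[c("ab", "ac", "bc", "abc")]), 0)

  ra <- random_callset(70, "A", seed = 41)
  rb <- random_callset(70, "B", seed = 42)
  rc <- random_callset(70, "C", seed = 43)
  v <- three_way_venn(ra, rb, rc)
  ka <- make_key(ra); kb <- make_key(rb); kc <- make_key(rc)
  for (k in union(union(ka, kb), kc)) {
    region <- paste0(
      if (k %in% ka) "a" else "", if (k %in% kb) "b" else "",
      if (k %in% kc) "c" else "")
    region <- if (nchar(region) == 1) paste0(region, "_only") else region
    expect_true(k %in% v[[region]])
  }
  cnt <- venn_counts(v)
  expect_equal(unname(cnt["a_only"] + cnt["ab"] + cnt["ac"] + cnt["abc"]),
               length(ka))
})

test_that("evolution-model summary computes reference-coverage fractions", {
  # construction: db1\db2 = 120 (95 in ref), db2\db1 = 59 (16 in ref)
  db1 <- keyset_callset(1:398, "GDSCish")
  db2 <- keyset_callset(c(1:278, 399:457), "CCLEish")     # shares 1:278
  ref <- keyset_callset(c(1:200, 279:373, 399:414, 500:600), "Tseq")
  v <- three_way_venn(db1, db2, ref)
  evo <- evolution_model_test(v, roles = c(reference = "Tseq",
                                           db1 = "GDSCish", db2 = "CCLEish"))
  row <- evo[evo$quantity == "pairwise_inconsistent_in_reference", ]
  expect_equal(row$numerator, 111)
  expect_equal(row$denominator, 179)
  expect_equal(row$pct, 62.0)
  expect_equal(evo$numerator[evo$quantity == "db1_exclusive_in_reference"], 95)
  expect_equal(evo$denominator[evo$quantity == "db1_exclusive_in_reference"], 120)

  # reference disjoint from both dbs -> all fractions 0
  ref0 <- keyset_callset(9000:9050, "T0")
  evo0 <- evolution_model_test(three_way_venn(db1, db2, ref0),
                               roles = c(reference = "T0", db1 = "GDSCish",
                                         db2 = "CCLEish"))
  expect_equal(evo0$fraction[1:3], c(0, 0, 0))
  expect_equal(evo0$numerator[evo0$quantity == "reference_only"], 51)

  # random instance agrees with brute-force membership
  ra <- random_callset(50, "A", seed = 61)
  rb <- random_callset(50, "B", seed = 62)
  rr <- random_callset(50, "R", seed = 63)
  evo_r <- evolution_model_test(three_way_venn(ra, rb, rr),
                                roles = c(reference = "R", db1 = "A", db2 = "B"))
  ka <- make_key(ra); kb <- make_key(rb); kr <- make_key(rr)
  d1x <- setdiff(ka, kb); d2x <- setdiff(kb, ka)
  expect_equal(evo_r$fraction[1], mean(d1x %in% kr))
  expect_equal(evo_r$fraction[2], mean(d2x %in% kr))
  expect_equal(evo_r$fraction[3],
               mean(c(d1x %in% kr, d2x %in% kr)))
})
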