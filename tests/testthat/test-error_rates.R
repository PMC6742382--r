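test_that("truth-set cutoff is inclusive and counts match brute force", {
  ref <- keyset_callset(1:3, "T", maf = c(0.05, 0.10, 0.50))
  ts <- build_truth_set(ref, 0.10)
  expect_equal(callset_size(ts$truth_calls), 2)
  expect_true(all(ts$truth_calls$calls$maf >= 0.10))
  expect_equal(callset_size(build_truth_set(callset(mk_calls(0), "E"))$truth_calls), 0)

  set.seed(77)
  mafs <- runif(1000, 0, 1)
  big <- keyset_callset(1:1000, "T", maf = mafs, depth = 10000)
  obs_maf <- big$calls$maf
  expect_equal(callset_size(build_truth_set(big, 0.10)$truth_calls),
               sum(obs_maf >= 0.10))
  # raising the cutoff never increases truth size
  sizes <- sapply(c(0.05, 0.1, 0.2, 0.4), function(ct)
    callset_size(build_truth_set(big, ct)$truth_calls))
  expect_true(all(diff(sizes) <= 0))
  expect_error(build_truth_set(ref, 1.5), class = "fnscope_config_error")
})

test_that("error report identities hold and the identity case is exact", {
  ref <- keyset_callset(1:200, "T", maf = 0.5)
  ts <- build_truth_set(ref)
  r <- error_report(ts$truth_calls, ts)
  expect_equal(r$p_tp, 1); expect_equal(r$p_fp, 0); expect_equal(r$p_fn, 0)
  expect_length(r$fn_keys, 0)

  db <- keyset_callset(c(1:150, 300:340), "DB", maf = 0.5)
  r2 <- error_report(db, ts)
  expect_equal(r2$p_tp + r2$p_fp, 1)
  expect_equal(r2$identification_rate + r2$p_fn, 1)
  expect_equal(length(r2$fn_keys), r2$n_truth - r2$n_confirmed)
  expect_gte(r2$adjusted_p_fp, 0)
  expect_lte(r2$adjusted_p_fp, r2$p_fp + 1e-12)

  expect_error(error_report(callset(mk_calls(0), "E"), ts),
               class = "fnscope_undefined_rate_error")
  empty_truth <- build_truth_set(keyset_callset(1:3, "T", maf = 0.01))
  expect_error(error_report(db, empty_truth),
               class = "fnscope_undefined_rate_error")
})

test_that("low-maf rescue adjusts the false-positive rate", {
  # reference: 100 high-maf calls + 8 low-maf calls (keys 101:108)
  ref <- combine_callsets(list(
    keyset_callset(1:100, "T", maf = 0.5),
    keyset_callset(101:108, "T", maf = 0.04)), "T")
  ts <- build_truth_set(ref)
  # db: 90 confirmed + 5 rescued low-maf + 5 novel
  db <- keyset_callset(c(1:90, 101:105, 201:205), "DB", maf = 0.5)
  r <- error_report(db, ts)
  expect_equal(r$n_db_only, 10)
  expect_equal(r$n_rescued, 5)
  expect_equal(r$adjusted_p_fp, 5 / 100)
})

test_that("adding calls to a database never decreases identification", {
  ref <- keyset_callset(1:300, "T", maf = 0.5)
  ts <- build_truth_set(ref)
  set.seed(13)
  base_ids <- sample(1:300, 120)
  db1 <- keyset_callset(base_ids, "D1", maf = 0.5)
  db2 <- keyset_callset(c(base_ids, sample(setdiff(1:300, base_ids), 50), 400:420),
                        "D2", maf = 0.5)
  r1 <- error_report(db1, ts)
  r2 <- error_report(db2, ts)
  expect_gte(r2$identification_rate, r1$identification_rate)
  comb <- combine_callsets(list(db1, db2), "D1/D2")
  expect_gte(error_report(comb, ts)$identification_rate, r1$identification_rate)
})

test_that("combining callsets takes the key union, first source wins", {
  a <- keyset_callset(1:398, "A", maf = 0.30)
  b <- keyset_callset(c(1:278, 399:457), "B", maf = 0.70)
  comb <- combine_callsets(list(a, b), "A/B")
  expect_equal(callset_size(comb), 457)
  # record for shared key 1 comes from the first source
  k1 <- make_key(keyset_callset(1, "x", maf = 0.30))
  expect_equal(comb$calls$maf[match(k1, make_key(comb))], 0.30)
  expect_equal(callset_size(combine_callsets(list(a), "solo")), 398)
  expect_error(combine_callsets(list(), "none"), class = "fnscope_config_error")

  r1 <- random_callset(90, "A", seed = 71)
  r2 <- random_callset(90, "B", seed = 72)
  r3 <- random_callset(90, "C", seed = 73)
  expect_equal(callset_size(combine_callsets(list(r1, r2, r3), "u")),
               length(union(union(make_key(r1), make_key(r2)), make_key(r3))))
})

test_that("gene profiles count, clamp and group per configuration", {
  truth_calls <- rbind(
    mk_calls(10, gene = "KRAS", pos = 1:10, alt_count = 500L, ref_count = 500L),
    mk_calls(5, gene = "BRD4", pos = 11:15, alt_count = 500L, ref_count = 500L),
    mk_calls(4, gene = "RARE", pos = 16:19, alt_count = 500L, ref_count = 500L))
  ts <- build_truth_set(callset(truth_calls, "T"))
  # db: all KRAS confirmed, no BRD4, all RARE
  db <- callset(truth_calls[c(1:10, 16:19), ], "DB")
  prof <- gene_error_profiles(ts, db)
  kras <- prof[prof$gene == "KRAS", ]
  expect_equal(kras$n_db, 10); expect_equal(kras$p_fn, 0)
  expect_equal(kras$group, "low")
  brd4 <- prof[prof$gene == "BRD4", ]
  expect_equal(brd4$n_db, 0); expect_equal(brd4$p_fn, 1)
  expect_equal(brd4$group, "high")
  expect_equal(prof$group[prof$gene == "RARE"], "excluded")
  # n_db counts only db calls confirmed in truth: extra db-only calls ignored
  db_extra <- combine_callsets(list(db, keyset_callset(900:905, "DB",
                                                       gene = "KRAS")), "DB")
  prof2 <- gene_error_profiles(ts, db_extra)
  expect_equal(prof2$n_db[prof2$gene == "KRAS"], 10)
  expect_true(all(prof2$p_fn >= 0 & prof2$p_fn <= 1))
})

test_that("candidate selection ranks genes and removes confirmed calls", {
  # plant reference-only clusters: G1 has 8, G2 has 5, G3 has 2
  genes <- rep(c("G1", "G2", "G3"), c(8, 5, 2))
  ref_only <- callset(mk_calls(15, gene = genes, pos = 1:15,
                               alt_count = 500L, ref_count = 500L), "T")
  confirmed_part <- keyset_callset(100:140, "T", gene = "G9")
  ref <- combine_callsets(list(ref_only, confirmed_part), "T")
  ts <- build_truth_set(ref)
  db <- keyset_callset(100:140, "DB", gene = "G9")
  sel <- select_validation_candidates(ts, list(db), list(), top_n_genes = 2)
  expect_equal(sel$gene_ranking$gene[1:2], c("G1", "G2"))
  expect_length(sel$selected, 13)
  # confirmation sets drop already-validated calls
  confirm <- callset(mk_calls(15, gene = genes, pos = 1:15,
                              alt_count = 500L, ref_count = 500L), "nDB")
  sel2 <- select_validation_candidates(ts, list(db), list(confirm), 2)
  expect_length(sel2$candidates, 0)
  # brute-force cross-check of the selection on a random instance
  set.seed(99)
  rnd <- random_callset(250, "T", seed = 99, maf_range = c(0.2, 0.9))
  ts_r <- build_truth_set(rnd)
  db_r <- random_callset(150, "DB", seed = 100, maf_range = c(0.2, 0.9))
  sel_r <- select_validation_candidates(ts_r, list(db_r), list(), 3)
  kt <- make_key(ts_r$truth_calls); kd <- make_key(db_r)
  ro <- !(kt %in% kd)
  cnt <- sort(table(ts_r$truth_calls$calls$gene[ro]), decreasing = TRUE)
  ordered <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  top <- ordered[1:3]
  expect_setequal(sel_r$candidates,
                  kt[ro & ts_r$truth_calls$calls$gene %in% top])
})
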