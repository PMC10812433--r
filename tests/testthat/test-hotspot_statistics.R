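test_that("aggregation counts per-complex presence and normalises per category", {
  recs <- list(
    ensemble_record("c1", category = "covalent", contacts = c(10, 20, 20, 30)),
    ensemble_record("c2", category = "strong_noncovalent", contacts = c(10, 40)))
  tab <- aggregate_contacts(recs)
  # residue 20 listed twice in c1 still scores one hit (presence counting)
  expect_equal(tab$hits_all[tab$residue == 20], 1)
  expect_equal(tab$hits_covalent[tab$residue == 10], 1)
  expect_equal(tab$hits_strong_noncovalent[tab$residue == 10], 1)
  expect_equal(sum(tab$pct_all), 100)
  expect_equal(sum(tab$pct_covalent), 100)

  solo <- aggregate_contacts(list(ensemble_record("x", contacts = 7)))
  expect_equal(solo$pct_all[solo$residue == 7], 100)

  expect_error(ensemble_record("c", category = "bogus"), "unknown category")
  expect_error(aggregate_contacts(recs, categories = "bogus"), "unknown")
})

test_that("percentages are invariant to duplicating every record", {
  recs <- make_ensemble(ensemble_spec(n_complexes = 10, seed = 4))
  t1 <- aggregate_contacts(recs)
  t2 <- aggregate_contacts(c(recs, recs))
  expect_equal(t2$pct_all, t1$pct_all)
  expect_equal(t2$hits_all, 2 * t1$hits_all)
})

test_that("empirical frequencies track planted probabilities (3-sigma)", {
  spec <- ensemble_spec(n_complexes = 200, receptor_length = 50,
                        planted = c(5, 25, 45), p_hot = 0.7, p_bg = 0.1,
                        seed = 13)
  tab <- aggregate_contacts(make_ensemble(spec))
  for (r in spec$planted) {
    hits <- tab$hits_all[tab$residue == r]
    expect_lt(abs(hits - 200 * 0.7), 3 * sqrt(200 * 0.7 * 0.3))
  }
  bg <- tab$hits_all[!(tab$residue %in% spec$planted)]
  expect_lt(abs(mean(bg) - 200 * 0.1), 3 * sqrt(200 * 0.1 * 0.9 / length(bg)))
})

test_that("hot-spot calling honours threshold, top-fraction and tie rules", {
  tab <- data.frame(residue = c(1, 2, 3),
                    hits_all = c(100, 9, 11), pct_all = c(10, 0.9, 1.1))
  class(tab) <- c("contact_frequency_table", class(tab))
  expect_equal(call_hotspots(tab, "all", percent_threshold = 1.0), c(1, 3))
  # equal percentages in top-fraction mode: ties kept, all returned
  tied <- data.frame(residue = 1:5, hits_all = rep(2, 5), pct_all = rep(20, 5))
  class(tied) <- c("contact_frequency_table", class(tied))
  expect_equal(call_hotspots(tied, "all", top_fraction = 0.2), 1:5)
  # monotone non-increasing in the threshold
  recs <- make_ensemble(ensemble_spec(seed = 3))
  t2 <- aggregate_contacts(recs)
  prev <- call_hotspots(t2, "all", 0)
  for (th in c(0.5, 1, 2, 5)) {
    cur <- call_hotspots(t2, "all", th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(call_hotspots(t2, "weak2"), "not in table")
})

test_that("venn partition is exhaustive, disjoint and correct on edge cases", {
  d <- venn_partition(1:5, 6:9)
  expect_equal(d$common, integer(0))
  i <- venn_partition(3:7, 3:7)
  expect_equal(i$only_C, integer(0))
  expect_equal(i$only_sNC, integer(0))
  expect_equal(i$common, 3:7)
  set.seed(2)
  for (k in 1:20) {
    a <- sample(100, sample(30, 1)); b <- sample(100, sample(30, 1))
    p <- venn_partition(a, b)
    expect_equal(length(intersect(p$only_C, p$only_sNC)), 0)
    expect_equal(length(intersect(p$only_C, p$common)), 0)
    expect_equal(length(intersect(p$only_sNC, p$common)), 0)
    expect_setequal(c(p$only_C, p$only_sNC, p$common), union(a, b))
  }
})

test_that("combination counting and adjacent-identical merging", {
  expect_identical(hotspot_combination_count(13, 7), 1716)
  expect_identical(hotspot_combination_count(5, 5), 1)
  expect_error(hotspot_combination_count(3, 7), "exceeds")
  # two Asp two positions apart and two adjacent Lys merge; 15 spots -> 13
  res <- c(1, 3, 10, 14, 30, 31, 35, 72, 73, 88, 92, 93, 94, 96, 103, 104)
  resn <- c("THR", "PHE", "ASP", "ARG", "TRP", "CYS", "LYS", "SER", "ALA",
            "LYS", "ILE", "LYS", "ASP", "ASP", "LYS", "LYS")
  merged <- merge_adjacent_identical(res, resn)
  expect_true(!96 %in% merged && 94 %in% merged)
  expect_true(!104 %in% merged && 103 %in% merged)
  expect_equal(length(merged), length(res) - 2)
})
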