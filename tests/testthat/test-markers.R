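test_that("hit filtering uses strict >90/>90 boundaries", {
  hits <- tibble::tibble(
    query_id = c("a", "b", "c", "d"), target_id = "s",
    identity = c(0.95, 0.90, 0.95, 0.89),
    coverage = c(0.92, 0.95, 0.90, 0.95),
    target_start = 0, target_end = 100, strand = "+"
  )
  kept <- filter_hits(hits)
  expect_equal(kept$query_id, "a")        # 0.90 exactly is rejected
})

test_that("hit filtering equals an independent predicate scan on random hits", {
  for (seed in c(101, 202)) {
    hits <- random_hits(100, seed)
    expect_equal(filter_hits(hits), oracle_filter_scan(hits))
  }
})

test_that("dual-map position merging follows the 30 cM rule", {
  expect_equal(merge_map_positions(10.0, 50.0), 10.0)   # >30 cM: keep published
  expect_equal(merge_map_positions(10.0, 20.0), 15.0)   # <=30 cM: average
  expect_equal(merge_map_positions(10.0, 40.0), 25.0)   # 30 exactly is concordant
  expect_equal(merge_map_positions(10.0, NA), 10.0)
  expect_equal(merge_map_positions(NA, 7.5), 7.5)
  expect_error(merge_map_positions(NA_real_, NA_real_), "no position")
})

test_that("marker placement tags multi-position markers and handles map membership", {
  hits <- tibble::tibble(
    query_id = c("m1", "m2", "m2", "m3", "m4"),
    target_id = c("s1", "s1", "s2", "s1", "s1"),
    identity = 1, coverage = 1,
    target_start = c(100, 200, 300, 400, 500),
    target_end = c(200, 300, 400, 500, 600), strand = "+"
  )
  map_pub <- tibble::tibble(marker_id = c("m1", "m2", "m4"),
                            linkage_group = c("LG1", "LG1", "LG1"),
                            cm = c(5, 10, 20))
  map_new <- tibble::tibble(marker_id = c("m2", "m4"),
                            linkage_group = c("LG1", "LG2"),
                            cm = c(12, 21))
  placed <- suppressMessages(place_markers(hits, map_pub, map_new))
  expect_equal(nrow(placed), 4L)                 # m3 dropped (in neither map)
  expect_equal(attr(placed, "dropped_unmapped"), "m3")
  m1 <- placed[placed$marker_id == "m1", ]
  expect_false(m1$ambiguous)
  expect_equal(m1$cm_resolved, 5)                # single-source position
  m2 <- placed[placed$marker_id == "m2", ]
  expect_equal(nrow(m2), 2L)                     # both alignments retained
  expect_true(all(m2$ambiguous))
  expect_equal(unique(m2$cm_resolved), 11)       # average of 10 and 12
  m4 <- placed[placed$marker_id == "m4", ]
  expect_true(m4$removed)                        # maps disagree on LG
  expect_equal(m4$removed_reason, "discordant_unresolvable")
})

test_that("every input marker ends in exactly one state", {
  hits <- random_hits(60, 7)
  hits$identity <- 0.99; hits$coverage <- 0.99
  ids <- unique(hits$query_id)
  map_pub <- tibble::tibble(marker_id = ids[1:30], linkage_group = "LG1",
                            cm = seq_len(30))
  map_new <- tibble::tibble(marker_id = ids[20:45],
                            linkage_group = rep(c("LG1", "LG2"), length.out = 26),
                            cm = seq_len(26))
  placed <- suppressMessages(place_markers(hits, map_pub, map_new))
  dropped <- attr(placed, "dropped_unmapped")
  state_of <- vapply(ids, function(m) {
    if (m %in% dropped) return("dropped")
    rows <- placed[placed$marker_id == m, ]
    if (all(rows$removed)) "removed" else "placed"
  }, character(1))
  expect_equal(sort(unique(c(placed$marker_id, dropped))), sort(ids))
  expect_true(all(state_of %in% c("placed", "removed", "dropped")))
})

test_that("unanimous scaffolds are placed with the mean cM key", {
  res <- resolve_scaffold_lg(marker_rows("s1", c("LG1", "LG1", "LG1"),
                                         c(5, 10, 15), c(1e3, 5e4, 9e4)))
  expect_equal(res$status, "placed")
  expect_equal(res$placement$cm_key, 10)
  expect_equal(res$placement$n_support_markers, 3L)
})

test_that("a single dissenting marker is removed and the majority wins", {
  m <- marker_rows("s1", c("LG1", "LG1", "LG2"), c(5, 10, 40),
                   c(1e3, 5e4, 9e4))
  res <- resolve_scaffold_lg(m)
  expect_equal(res$status, "placed")
  expect_equal(res$placement$linkage_group, "LG1")
  expect_equal(res$removed_marker_ids, "s1_m03")
})

test_that("coordinate-separated linkage groups split at the innermost midpoint", {
  m <- marker_rows("s1", c("LG1", "LG1", "LG2", "LG2"), c(5, 10, 3, 8),
                   c(10e3, 20e3, 80e3, 90e3))
  res <- resolve_scaffold_lg(m)
  expect_equal(res$status, "split")
  expect_equal(res$split$split_pos, 50000)
  expect_equal(res$split$left_lg, "LG1")
  expect_equal(res$split$right_lg, "LG2")
  # brute-force check: the midpoint separates the two groups perfectly
  expect_true(all(m$scaffold_pos[m$linkage_group == "LG1"] < 50000))
  expect_true(all(m$scaffold_pos[m$linkage_group == "LG2"] > 50000))
})

test_that("interleaved, 1-vs-1 and empty marker sets are unplaceable", {
  inter <- marker_rows("s1", c("LG1", "LG2", "LG1", "LG2"), c(5, 3, 10, 8),
                       c(1e4, 2e4, 3e4, 4e4))
  res <- resolve_scaffold_lg(inter)
  expect_equal(res$status, "unplaceable")
  expect_true(res$interleaved)

  res2 <- resolve_scaffold_lg(marker_rows("s1", c("LG1", "LG2"), c(5, 3),
                                          c(1e4, 2e4)))
  expect_equal(res2$status, "unplaceable")
  expect_false(res2$interleaved)

  res3 <- resolve_scaffold_lg(marker_rows("s1", character(), numeric(),
                                          numeric()))
  expect_equal(res3$status, "unplaceable")
})

test_that("a single interloper inside a chimera is removed side-wise and the split stands", {
  m <- marker_rows("s1", c("LG1", "LG1", "LG1", "LG2", "LG2", "LG2"),
                   c(5, 10, 12, 3, 8, 9),
                   c(10e3, 20e3, 30e3, 80e3, 90e3, 95e3))
  # an LG2 marker sitting inside the LG1 segment
  m <- dplyr::bind_rows(m, marker_rows("s1", "LG2", 6, 15e3))
  m$marker_id <- sprintf("m%02d", seq_len(nrow(m)))
  res <- resolve_scaffold_lg(m)
  expect_equal(res$status, "split")
  expect_equal(res$split$left_lg, "LG1")
  expect_equal(res$split$right_lg, "LG2")
  expect_equal(res$removed_marker_ids, "m07")
  expect_true(res$split$split_pos > 30e3 && res$split$split_pos < 80e3)
})

test_that("ambiguous markers never decide a linkage group alone", {
  solo <- marker_rows("s1", "LG1", 5, 1e4, ambiguous = TRUE)
  expect_equal(resolve_scaffold_lg(solo)$status, "unplaceable")
  pair <- marker_rows("s1", c("LG1", "LG1"), c(5, 9), c(1e4, 3e4),
                      ambiguous = TRUE)
  expect_equal(resolve_scaffold_lg(pair)$status, "placed")
  # unambiguous markers out-vote ambiguous ones
  mixed <- dplyr::bind_rows(
    marker_rows("s1", "LG2", 4, 2e4),
    marker_rows("s2", c("LG1", "LG1"), c(5, 9), c(1e4, 3e4), ambiguous = TRUE)
  )
  mixed$scaffold_id <- "s1"
  expect_equal(resolve_scaffold_lg(mixed)$placement$linkage_group, "LG2")
})

test_that("scaffold resolution is invariant to marker order", {
  m <- marker_rows("s1", c("LG1", "LG1", "LG2", "LG2", "LG1"),
                   c(5, 10, 3, 8, 7), c(1e4, 2e4, 8e4, 9e4, 3e4))
  base <- resolve_scaffold_lg(m)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, m[sample.int(nrow(m)), ])
    res <- resolve_scaffold_lg(perm)
    expect_equal(res$status, base$status)
    expect_equal(res$split$split_pos, base$split$split_pos)
    expect_equal(sort(res$removed_marker_ids), sort(base$removed_marker_ids))
  }
})

test_that("splitting a scaffold conserves sequence and shifts right-side markers", {
  seqs <- Biostrings::DNAStringSet(c(p = paste(rep("ACGT", 25000), collapse = "")))
  splits <- tibble::tibble(scaffold_id = "p", split_pos = 50000,
                           left_lg = "LG1", right_lg = "LG2",
                           interleaved = FALSE)
  markers <- marker_rows("p", c("LG1", "LG2"), c(5, 3), c(20e3, 80e3))
  out <- apply_splits(seqs, splits, markers)
  expect_equal(unname(Biostrings::width(out$sequences)), c(50000, 50000))
  expect_equal(sum(Biostrings::width(out$sequences)), 100000)
  m2 <- out$markers[out$markers$scaffold_id == "p_2", ]
  expect_equal(m2$scaffold_pos, 30000)
  expect_equal(out$markers$scaffold_id[1], "p_1")

  bad <- splits; bad$split_pos <- 0
  expect_error(apply_splits(seqs, bad), "outside")
})
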