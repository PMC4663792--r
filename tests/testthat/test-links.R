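memberships_for <- function(hits) {
  tibble::tibble(bac_id = unique(hits$bac_id),
                 contig_id = hits$contig_id[match(unique(hits$bac_id),
                                                  hits$bac_id)],
                 singleton = FALSE)
}

test_that("explicitly named sink contigs lose all their hits", {
  hits <- dplyr::bind_rows(hits_for_counts("s1", list(C1 = 3)),
                           hits_for_counts("s2", list(C2 = 3)))
  mem <- memberships_for(hits)
  out <- suppressMessages(
    filter_sink_contigs(hits[, 1:7], mem, explicit_ids = "C1", auto = FALSE))
  expect_equal(unique(out$contig_id), "C2")
  expect_equal(attr(out, "sink_contigs"), "C1")
})

test_that("a high-degree contig is auto-detected on the {2,2,3,3,40} degree profile", {
  degrees <- c(A = 2, B = 2, C = 3, D = 3, SINK = 40)
  rows <- list()
  for (ct in names(degrees)) {
    for (s in seq_len(degrees[[ct]])) {
      rows[[paste(ct, s)]] <- hits_for_counts(sprintf("scaf_%s_%02d", ct, s),
                                              stats::setNames(list(1), ct))
    }
  }
  hits <- dplyr::bind_rows(rows)
  hits$bac_id <- hits$query_id <- sprintf("b%03d_1", seq_len(nrow(hits)))
  hits$bac_id <- sub("_1$", "", hits$query_id)
  mem <- tibble::tibble(bac_id = hits$bac_id, contig_id = hits$contig_id,
                        singleton = FALSE)
  out <- suppressMessages(filter_sink_contigs(hits[, 1:7], mem, auto = TRUE))
  expect_equal(attr(out, "sink_contigs"), "SINK")
  expect_false("SINK" %in% out$contig_id)
})

test_that("sink filtering with auto off and no explicit list is the identity", {
  hits <- hits_for_counts("s1", list(C1 = 4, C2 = 2))
  mem <- memberships_for(hits)
  out <- suppressMessages(filter_sink_contigs(hits[, 1:7], mem,
                                              explicit_ids = character(),
                                              auto = FALSE))
  expect_equal(nrow(out), nrow(hits))
  expect_equal(attr(out, "sink_contigs"), character(0))
})

test_that("link classification reproduces the unique/dominant/strong/tie patterns", {
  cases <- list(
    list(counts = list(C1 = 5), expect = "unique"),
    list(counts = list(C1 = 6, C2 = 2, C3 = 1), expect = "dominant"),
    list(counts = list(C1 = 4, C2 = 2, C3 = 2), expect = "strong"),
    list(counts = list(C1 = 2, C2 = 2), expect = "rejected"),
    list(counts = list(C1 = 1), expect = "rejected")   # below min_total_unique
  )
  for (cs in cases) {
    hits <- hits_for_counts("s1", cs$counts)
    call <- classify_links(hits)
    expect_equal(call$category, cs$expect)
    expect_equal(call$n_total, sum(unlist(cs$counts)))
  }
})

test_that("classification is order-invariant, exclusive and matches a predicate scan", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      k <- sample(1:4, 1)
      counts <- stats::setNames(as.list(sample(1:7, k, replace = TRUE)),
                                paste0("C", seq_len(k)))
      hits <- hits_for_counts("sx", counts)
      call <- classify_links(hits)
      expect_equal(call$category,
                   oracle_classify_counts(unlist(counts)))
      perm <- hits[sample.int(nrow(hits)), ]
      expect_equal(classify_links(perm), call)
      expect_true(call$category %in%
                    c("unique", "dominant", "strong", "rejected"))
    }
  })
})

placements_s2_s5 <- tibble::tibble(
  scaffold_id = c("S2", "S5"), linkage_group = c("LG1", "LG3"),
  cm_key = c(12, 40), orientation = "+", evidence = "marker",
  split_of = NA_character_, n_support_markers = 3L
)

test_that("an unplaced scaffold is propagated through a shared contig", {
  links <- tibble::tibble(
    scaffold_id = c("S2", "S9"), contig_id = "C7",
    n_total = c(5L, 3L), n_to_contig = c(5L, 3L),
    category = c("unique", "strong")
  )
  out <- suppressMessages(propagate_placement(links, placements_s2_s5[1, ]))
  expect_equal(out$scaffold_id, "S9")
  expect_equal(out$anchor_id, "S2")
  expect_equal(out$linkage_group, "LG1")
  expect_equal(out$cm_key, 12)
  expect_equal(out$orientation, "?")
  expect_equal(out$evidence, "bac_link")
})

test_that("propagation abstains without an anchor or on conflicting neighbours", {
  links_lonely <- tibble::tibble(scaffold_id = "S9", contig_id = "C7",
                                 n_total = 3L, n_to_contig = 3L,
                                 category = "strong")
  out <- suppressMessages(propagate_placement(links_lonely, placements_s2_s5))
  expect_equal(nrow(out), 0L)

  links_conflict <- tibble::tibble(
    scaffold_id = c("S2", "S5", "S9"), contig_id = "C7",
    n_total = c(5L, 5L, 3L), n_to_contig = c(5L, 5L, 3L),
    category = c("unique", "unique", "strong")
  )
  expect_warning(out2 <- propagate_placement(links_conflict, placements_s2_s5),
                 "disagree")
  expect_equal(nrow(out2), 0L)
})

test_that("propagation never moves a placed scaffold and never places one twice", {
  links <- tibble::tibble(
    scaffold_id = c("S2", "S5", "S9", "S9"),
    contig_id = c("C7", "C8", "C7", "C8"),
    n_total = c(5L, 4L, 3L, 3L), n_to_contig = c(5L, 4L, 3L, 3L),
    category = c("unique", "unique", "strong", "strong")
  )
  # S9 has accepted links to two contigs anchored by different scaffolds
  # of the same linkage group: it must be placed exactly once
  pl <- placements_s2_s5
  pl$linkage_group <- "LG1"
  out <- suppressMessages(propagate_placement(links, pl))
  expect_equal(sum(out$scaffold_id == "S9"), 1L)
  expect_false(any(out$scaffold_id %in% pl$scaffold_id))
})
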