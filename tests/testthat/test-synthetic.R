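test_that("genome simulation is seed-deterministic and honours its parameters", {
  g1 <- simulate_genome(2, c(50e3, 80e3), gc = 0.4, seed = 5)
  g2 <- simulate_genome(2, c(50e3, 80e3), gc = 0.4, seed = 5)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_equal(unname(Biostrings::width(g1$sequences)), c(50e3, 80e3))
  gc_only <- simulate_genome(1, 10e3, gc = 1.0, seed = 5)
  freq <- Biostrings::alphabetFrequency(gc_only$sequences)[1, c("A", "T")]
  expect_equal(sum(freq), 0)
})

test_that("scaffolds tile the chromosomes and reconstruct them exactly", {
  genome <- simulate_genome(2, 200e3, seed = 8)
  frag <- fragment_genome(genome, seed = 9)
  tr <- frag$truth
  for (ch in unique(tr$chrom)) {
    p <- tr[tr$chrom == ch, ]
    p <- p[order(p$chrom_start), ]
    expect_equal(p$chrom_start[1], 0)
    expect_equal(p$chrom_end[nrow(p)], 200e3)
    expect_equal(p$chrom_start[-1], p$chrom_end[-nrow(p)])  # no overlap, no gap
    rebuilt <- paste(vapply(seq_len(nrow(p)), function(i) {
      s <- as.character(frag$sequences[[p$scaffold_id[i]]])
      s <- substr(s, p$scaf_start[i] + 1, p$scaf_end[i])
      if (p$orientation[i] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      } else s
    }, character(1)), collapse = "")
    expect_equal(rebuilt, as.character(genome$sequences[[ch]]))
  }
  expect_true(all(tr$chrom_end - tr$chrom_start >= 5000))
  frag2 <- fragment_genome(genome, seed = 9)
  expect_identical(as.character(frag$sequences), as.character(frag2$sequences))
})

test_that("chimeric scaffolds join two chromosomes with a recorded breakpoint", {
  genome <- simulate_genome(3, 500e3, seed = 12)
  frag <- fragment_genome(genome, n_chimeric = 2, seed = 13)
  chim <- frag$truth[frag$truth$chimeric, ]
  expect_equal(length(unique(chim$scaffold_id)), 2L)
  for (id in unique(chim$scaffold_id)) {
    p <- chim[chim$scaffold_id == id, ]
    expect_equal(nrow(p), 2L)
    expect_false(p$chrom[1] == p$chrom[2])
    expect_equal(p$scaf_end[1], p$scaf_start[2])   # breakpoint
    expect_equal(length(frag$sequences[[id]]), p$scaf_end[2])
  }
})

test_that("noise-free maps are identical, monotone, and alignments pass the filter", {
  genome <- simulate_genome(2, 1e6, seed = 21)
  frag <- fragment_genome(genome, seed = 22)
  maps <- simulate_maps(frag, genome, n_markers = 100, noise_cm_sd = 0,
                        frac_published_only = 0, frac_new_only = 0, seed = 23)
  pub <- maps$map_published[order(maps$map_published$marker_id), ]
  new <- maps$map_new[order(maps$map_new$marker_id), ]
  expect_equal(pub$cm, new$cm)
  expect_equal(pub$linkage_group, new$linkage_group)
  # cM increases with bp within each chromosome
  tr <- maps$truth[order(maps$truth$chrom, maps$truth$pos), ]
  for (ch in unique(tr$chrom)) {
    expect_true(all(diff(tr$true_cm[tr$chrom == ch]) >= 0))
  }
  f <- withr::local_tempfile()
  write_psl(maps$psl, f)
  hits <- read_psl(f)
  expect_equal(nrow(filter_hits(hits)), nrow(hits))
})

test_that("corruption fractions are realized at exactly the rounded counts", {
  genome <- simulate_genome(3, 1e6, seed = 31)
  frag <- fragment_genome(genome, seed = 32)
  maps <- simulate_maps(frag, genome, n_markers = 200,
                        frac_wrong_lg = 0.05, frac_discordant = 0.10,
                        frac_multimap = 0.05, seed = 33)
  expect_equal(sum(maps$truth$corruption == "wrong_lg"), 10L)
  expect_equal(sum(maps$truth$corruption == "discordant_cm"), 20L)
  expect_equal(sum(maps$truth$corruption == "multi_map"), 10L)
  # each multi-mapper contributes a second alignment
  expect_equal(nrow(maps$psl), 200L + 10L)
  # discordant markers disagree by more than 30 cM between the maps
  disc <- maps$truth$marker_id[maps$truth$corruption == "discordant_cm"]
  both <- dplyr::inner_join(maps$map_published, maps$map_new,
                            by = "marker_id", suffix = c("_p", "_n"))
  d <- both[both$marker_id %in% disc, ]
  expect_true(all(abs(d$cm_p - d$cm_n) > 30))
})

test_that("BAC evidence files are read back loss-free and the sink dominates degree", {
  genome <- simulate_genome(3, 1e6, seed = 41)
  frag <- fragment_genome(genome, seed = 42)
  bacs <- simulate_bacs(frag, genome, n_contigs = 40, n_singletons = 20,
                        n_sink_contigs = 1, seed = 43)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_blast6(bacs$blast6, f1)
  readr::write_tsv(bacs$memberships, f2, progress = FALSE)
  hits <- read_blast6(f1, bacs$query_lengths)
  expect_equal(nrow(hits), nrow(bacs$blast6))
  mem <- read_physical_map(f2)
  expect_equal(sum(mem$singleton), 20L)
  # the sink contig's scaffold degree exceeds every genuine contig's
  kept <- filter_hits(hits)
  kept$bac_id <- bac_end_to_bac(kept$query_id)
  kept$contig_id <- mem$contig_id[match(kept$bac_id, mem$bac_id)]
  kept <- kept[!is.na(kept$contig_id), ]
  deg <- tapply(kept$target_id, kept$contig_id,
                function(s) length(unique(s)))
  sink_id <- unique(bacs$truth$contig_id[bacs$truth$sink])
  expect_equal(names(which.max(deg)), sink_id)
  # both ends of a genuine clone land on scaffolds of the same chromosome
  genuine <- kept[!kept$contig_id %in% sink_id, ]
  tr <- frag$truth
  chrom_of <- tr$chrom[match(genuine$target_id, tr$scaffold_id)]
  by_bac <- split(chrom_of, genuine$bac_id)
  expect_true(all(vapply(by_bac, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("the no-noise population limit recovers founder-drawn genotypes", {
  genome <- simulate_genome(2, 1e6, seed = 51)
  pop <- simulate_population(genome, n_founders = 4, n_generations = 0,
                             n_individuals = 20, mean_depth = 60,
                             error_rate = 0, n_sites = 100, seed = 52)
  gm <- call_genotypes(pop$depths)
  called <- gm$genotype
  truth <- pop$truth$genotype
  ok <- !is.na(called)
  expect_gt(mean(ok), 0.99)            # depth 60: essentially everything called
  expect_equal(called[ok], truth[ok])
  pop2 <- simulate_population(genome, n_founders = 4, n_generations = 0,
                              n_individuals = 20, mean_depth = 60,
                              error_rate = 0, n_sites = 100, seed = 52)
  expect_identical(pop$depths$alt_depth, pop2$depths$alt_depth)
})

test_that("feeding truth back into the evaluator yields perfect metrics", {
  genome <- simulate_genome(2, 500e3, seed = 61)
  frag <- fragment_genome(genome, seed = 62)
  tr <- frag$truth
  pl <- tr |>
    dplyr::mutate(linkage_group = sub("^chr", "LG", .data$chrom),
                  cm_key = .data$chrom_start, evidence = "marker",
                  split_of = NA_character_, n_support_markers = 2L) |>
    dplyr::select(scaffold_id, linkage_group, cm_key,
                  orientation, evidence, split_of, n_support_markers)
  ord <- order_scaffolds(pl)
  ev <- evaluate_anchoring(ord, tr)
  expect_equal(ev$metrics$placed_fraction, 1)
  expect_equal(ev$metrics$chrom_accuracy, 1)
  expect_equal(ev$metrics$order_rank_correlation, 1)
  expect_equal(ev$metrics$orientation_accuracy, 1)
  # an empty placement set scores zero coverage
  ev0 <- evaluate_anchoring(ord[0, ], tr)
  expect_equal(ev0$metrics$placed_fraction, 0)
})

test_that("a randomly permuted order scores near-zero rank correlation", {
  genome <- simulate_genome(1, 800e3, seed = 71)
  frag <- fragment_genome(genome, seed = 72)
  tr <- frag$truth
  withr::with_seed(73, {
    pl <- tibble::tibble(
      scaffold_id = sample(tr$scaffold_id), linkage_group = "LG1",
      cm_key = seq_len(nrow(tr)), orientation = "?", evidence = "marker",
      split_of = NA_character_, n_support_markers = 2L
    )
  })
  ev <- evaluate_anchoring(order_scaffolds(pl), tr)
  expect_lt(abs(ev$metrics$order_rank_correlation), 0.5)
})
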