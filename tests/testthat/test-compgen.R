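# 100-site alignment with a prescribed number of transitions/transversions
pair_with <- function(n_sites, n_transition, n_transversion) {
  a <- rep("A", n_sites)
  b <- a
  if (n_transition > 0) b[seq_len(n_transition)] <- "G"
  if (n_transversion > 0) {
    b[n_transition + seq_len(n_transversion)] <- "C"
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("K2P matches the closed form on the (P, Q) = (0.10, 0.05) case", {
  p <- pair_with(100, 10, 5)
  res <- kimura2p(p$a, p$b)
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  expect_equal(res$n_sites, 100L)
  # hand evaluation of -1/2 * ln(0.75 * sqrt(0.90))
  expect_equal(res$K, -0.5 * log(0.75 * sqrt(0.90)), tolerance = 1e-9)
})

test_that("identical sequences have zero divergence and saturation errors out", {
  res <- kimura2p("ACGTACGT", "ACGTACGT")
  expect_equal(res$K, 0)
  expect_equal(res$P + res$Q, 0)
  sat <- pair_with(100, 50, 0)
  expect_error(kimura2p(sat$a, sat$b), "saturation")
  expect_error(kimura2p("----", "----"), "no comparable")
  expect_error(kimura2p("ACGT", "ACG"), "equal length")
})

test_that("gapped and ambiguous columns are excluded from the site count", {
  res <- kimura2p("ACGT-NA", "ACGTTTA")
  expect_equal(res$n_sites, 5L)
})

test_that("K2P is symmetric and agrees with the phylogenetics reference", {
  skip_if_not_installed("ape")
  withr::with_seed(99, {
    for (rep in 1:10) {
      n <- 300
      a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      b <- a
      mut <- sample(n, 30)
      b[mut] <- vapply(b[mut], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
      mine <- kimura2p(sa, sb)
      flipped <- kimura2p(sb, sa)
      expect_equal(mine$K, flipped$K)
      bin <- ape::as.DNAbin(matrix(c(tolower(a), tolower(b)), nrow = 2,
                                   byrow = TRUE))
      expect_equal(mine$K, as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-12)
    }
  })
})

test_that("K is monotone in P at fixed Q and matches P + Q to first order", {
  q <- 0.02
  ks <- vapply(seq(0.01, 0.30, by = 0.01), function(p) {
    pr <- pair_with(200, round(200 * p), round(200 * q))
    kimura2p(pr$a, pr$b)$K
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  for (pq in list(c(0.02, 0.01), c(0.03, 0.02), c(0.01, 0.01))) {
    pr <- pair_with(200, round(200 * pq[1]), round(200 * pq[2]))
    res <- kimura2p(pr$a, pr$b)
    expect_lt(abs(res$K - (res$P + res$Q)) / (res$P + res$Q), 0.05)
  }
})

test_that("LTR insertion age is K over twice the substitution rate", {
  expect_equal(ltr_insertion_time(0.26, 1.3e-8), 1.0e7)
  expect_equal(ltr_insertion_time(0), 0)
  expect_error(ltr_insertion_time(0.1, 0), "positive")
  expect_error(ltr_insertion_time(-0.1), "non-negative")
})

collinear_anchors <- function(n, chrom_a = "ca", chrom_b = "cb",
                              inverted = FALSE) {
  tibble::tibble(
    gene_a = sprintf("ga%02d", seq_len(n)), chrom_a = chrom_a,
    index_a = seq_len(n),
    gene_b = sprintf("gb%02d", seq_len(n)), chrom_b = chrom_b,
    index_b = if (inverted) (n + 1) - seq_len(n) else seq_len(n)
  )
}

test_that("the 30-pair threshold separates blocks from noise", {
  expect_equal(nrow(call_synteny_blocks(collinear_anchors(30))), 1L)
  b <- call_synteny_blocks(collinear_anchors(30))
  expect_equal(b$n_anchors, 30L)
  expect_equal(b$direction, "forward")
  expect_equal(nrow(call_synteny_blocks(collinear_anchors(29))), 0L)
})

test_that("inverted blocks are detected", {
  b <- call_synteny_blocks(collinear_anchors(35, inverted = TRUE))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_anchors, 35L)
  expect_equal(b$direction, "inverted")
})

test_that("duplicate anchor pairs are deduplicated with a report", {
  a <- collinear_anchors(30)
  expect_message(b <- call_synteny_blocks(dplyr::bind_rows(a, a[1, ])),
                 "duplicate")
  expect_equal(b$n_anchors, 30L)
})

test_that("chaining equals the brute-force longest monotone chain on random instances", {
  withr::with_seed(1234, {
    for (rep in 1:60) {
      n <- sample(5:40, 1)
      gap <- sample(2:6, 1)
      anchors <- tibble::tibble(
        gene_a = sprintf("a%02d", seq_len(n)), chrom_a = "c1",
        index_a = sample(seq_len(3 * n), n),
        gene_b = sprintf("b%02d", seq_len(n)), chrom_b = "c2",
        index_b = sample(seq_len(3 * n), n)
      )
      blocks <- call_synteny_blocks(anchors, min_pairs = 1L,
                                    max_rank_gap = gap)
      expect_equal(max(blocks$n_anchors),
                   oracle_longest_chain(anchors$index_a, anchors$index_b, gap))
    }
  })
})

test_that("divergence histogram bins half-open and reports the modal bin", {
  h <- divergence_histogram(c(0.149, 0.151, 0.31), bin_width = 0.01)
  # hand binning: 0.149 -> [0.14, 0.15); 0.151 -> [0.15, 0.16); 0.31 -> [0.31, 0.32)
  expect_equal(h$count[h$bin_lo == 0.14], 1L)
  expect_equal(h$count[abs(h$bin_lo - 0.15) < 1e-9], 1L)
  expect_equal(h$count[abs(h$bin_lo - 0.31) < 1e-9], 1L)
  expect_equal(sum(h$count), 3L)
  # tie for the mode goes to the smaller bin
  expect_equal(modal_bin(h)$bin_lo, 0.14)

  expect_error(divergence_histogram(numeric()), "no values")
  h2 <- divergence_histogram(rep(0.1503, 5), bin_width = 0.01)
  expect_equal(nrow(h2[h2$count > 0, ]), 1L)
  expect_equal(modal_bin(h2)$count, 5L)
})
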