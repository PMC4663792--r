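# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately written as directly as possible (plain loops,
# closed forms) so it shares no code with the implementation it checks.

# one-line predicate scan for the alignment filter
oracle_filter_scan <- function(hits, min_identity = 0.90, min_coverage = 0.90) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- hits$identity[i] > min_identity && hits$coverage[i] > min_coverage
  }
  hits[keep, ]
}

# random alignment-hit table
random_hits <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      query_id = sprintf("q%03d", seq_len(n)),
      target_id = sample(sprintf("s%02d", 1:10), n, replace = TRUE),
      identity = round(runif(n, 0.80, 1.0), 3),
      coverage = round(runif(n, 0.80, 1.0), 3),
      target_start = floor(runif(n, 0, 1000)),
      target_end = floor(runif(n, 1001, 2000)),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

# brute-force longest gap-constrained strictly monotone chain over anchors,
# both directions, via longest-path recursion on the precedence DAG
oracle_longest_chain <- function(index_a, index_b, max_rank_gap) {
  n <- length(index_a)
  if (n == 0L) return(0L)
  longest_from <- function(sgn) {
    ord <- order(index_a)
    ia <- index_a[ord]; ib <- sgn * index_b[ord]
    memo <- rep(NA_integer_, n)
    rec <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      best <- 1L
      for (j in seq_len(n)) {
        da <- ia[j] - ia[i]; db <- ib[j] - ib[i]
        if (da >= 1 && da <= max_rank_gap && db >= 1 && db <= max_rank_gap) {
          best <- max(best, 1L + rec(j))
        }
      }
      memo[i] <<- best
      best
    }
    max(vapply(seq_len(n), rec, integer(1)))
  }
  max(longest_from(1), longest_from(-1))
}

# classification predicate scan: evaluates the three link rules directly on
# a named count vector
oracle_classify_counts <- function(counts, min_total_unique = 2,
                                   min_total_dominant = 4, strong_ratio = 2,
                                   strong_min = 3) {
  counts <- sort(counts, decreasing = TRUE)
  total <- sum(counts)
  top <- counts[1]
  second <- if (length(counts) > 1) counts[2] else 0
  if (length(counts) > 1 && counts[2] == top) return("rejected")
  if (length(counts) == 1 && total >= min_total_unique) return("unique")
  if (top / total > 0.5 && total >= min_total_dominant &&
      length(counts) > 1) return("dominant")
  if (top >= strong_ratio * second && top >= strong_min &&
      length(counts) > 1) return("strong")
  "rejected"
}

# build an alignment-hit table for BAC ends realizing given per-contig
# counts on one scaffold (contig membership handled separately)
hits_for_counts <- function(scaffold, counts) {
  rows <- list()
  k <- 0
  for (ct in names(counts)) {
    for (i in seq_len(counts[[ct]])) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        query_id = sprintf("%s_bac%02d_1", ct, i),
        target_id = scaffold, identity = 0.99, coverage = 0.99,
        target_start = k * 100, target_end = k * 100 + 50, strand = "+",
        bac_id = sprintf("%s_bac%02d", ct, i), contig_id = ct
      )
    }
  }
  dplyr::bind_rows(rows)
}

# tiny genotype matrix from explicit depth matrices
gm_from_depths <- function(ref, alt, chrom = "chr1", pos = NULL) {
  n <- nrow(ref)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  colnames(ref) <- colnames(alt) <- sprintf("ind%02d", seq_len(ncol(ref)))
  genotype_matrix(
    tibble::tibble(chrom = rep(chrom, n), pos = pos,
                   ref = rep("A", n), alt = rep("G", n)),
    ref, alt
  )
}

# placed-marker tibble builder for resolver tests
marker_rows <- function(scaffold_id, lgs, cms, pos, ambiguous = FALSE) {
  n <- length(lgs)
  tibble::tibble(
    marker_id = sprintf("%s_m%02d", scaffold_id, seq_len(n)),
    scaffold_id = scaffold_id, scaffold_pos = pos, linkage_group = lgs,
    cm_published = cms, cm_new = cms, cm_resolved = cms,
    ambiguous = rep_len(ambiguous, n), removed = FALSE, removed_reason = "none"
  )
}

# default corrupted scenario of the recovery tests
corrupted_config <- function(seed) {
  list(seed = seed, scenario = list(
    frac_wrong_lg = 0.05, frac_multimap = 0.05, frac_discordant = 0.10,
    n_chimeric = 5L, n_sink_contigs = 1L
  ))
}
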