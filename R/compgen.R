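#' Kimura two-parameter divergence between two aligned sequences
#'
#' Compares sites where both sequences carry an unambiguous base (A, C, G
#' or T); gapped or ambiguous columns are excluded. With transition
#' proportion P (A<->G, C<->T) and transversion proportion Q over the
#' compared sites, the divergence is
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character strings
#'   or [Biostrings::DNAString]-like).
#' @return A one-row tibble with `P`, `Q`, `K` and `n_sites`.
#' @export
kimura2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(as.character(seq_a)), "")[[1]]
  b <- strsplit(toupper(as.character(seq_b)), "")[[1]]
  if (length(a) != length(b)) {
    abort("aligned sequences must have equal length")
  }
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[valid]; b <- b[valid]
  n <- length(a)
  if (n == 0L) abort("no comparable sites (all gapped or ambiguous)")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf("K2P saturation: P = %.3f, Q = %.3f outside the model domain", P, Q))
  }
  tibble(P = P, Q = Q, K = -0.5 * log(w1 * sqrt(w2)), n_sites = n)
}

#' Estimate LTR insertion time from divergence
#'
#' The 5' and 3' long terminal repeats of a retrotransposon are identical
#' at insertion and diverge independently afterwards, so the insertion age
#' is `T = K / (2 * rate)` with `rate` the substitution rate per site per
#' year.
#'
#' @param K Kimura two-parameter divergence between the two LTRs.
#' @param rate Substitution rate per site per year.
#' @return Insertion time(s) in years.
#' @export
ltr_insertion_time <- function(K, rate = 1.3e-8) {
  if (any(rate <= 0)) abort("substitution rate must be positive")
  if (any(K < 0)) abort("divergence must be non-negative")
  K / (2 * rate)
}

#' Call collinearity (synteny) blocks from gene-anchor pairs
#'
#' Anchors are orthologous gene pairs ranked along a chromosome of each
#' genome. Within each chromosome pair, the longest strictly monotone
#' chain (increasing ranks on both genomes for forward blocks, increasing
#' on A and decreasing on B for inverted ones) with consecutive-anchor
#' rank gaps of at most `max_rank_gap` on both genomes is extracted, the
#' anchors are removed, and extraction repeats while chains of at least
#' `min_pairs` anchors remain. Overlap is thereby resolved in favour of
#' the longer chain; length ties go to the chain starting at the smaller
#' rank on genome A. Duplicate (gene_a, gene_b) pairs are deduplicated
#' with a reported count.
#'
#' @param anchors Tibble with columns `gene_a`, `chrom_a`, `index_a`,
#'   `gene_b`, `chrom_b`, `index_b` (per-chromosome gene ranks). If
#'   `index_*` are missing but `start_*` are present, ranks are computed
#'   from the start coordinates.
#' @param min_pairs Minimum anchors per block.
#' @param max_rank_gap Maximum rank gap between consecutive block anchors.
#' @return A tibble of blocks: `block_id`, `chrom_a`, `chrom_b`,
#'   `direction`, `n_anchors`, rank spans on both genomes, and a
#'   list-column `anchors` holding each block's anchor rows.
#' @export
call_synteny_blocks <- function(anchors, min_pairs = 30L, max_rank_gap = 5L) {
  anchors <- rank_anchors(anchors)
  dup <- duplicated(anchors[c("gene_a", "gene_b")])
  if (any(dup)) {
    inform(sprintf("synteny: removed %d duplicate anchor pair(s)", sum(dup)))
    anchors <- anchors[!dup, ]
  }
  groups <- unique(anchors[c("chrom_a", "chrom_b")])
  groups <- groups[order(groups$chrom_a, groups$chrom_b), ]
  blocks <- list()
  for (g in seq_len(nrow(groups))) {
    pool <- anchors[anchors$chrom_a == groups$chrom_a[g] &
                      anchors$chrom_b == groups$chrom_b[g], ]
    repeat {
      best <- best_chain(pool, max_rank_gap)
      if (is.null(best) || length(best$idx) < min_pairs) break
      chain <- pool[best$idx, ]
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = chain$chrom_a[1], chrom_b = chain$chrom_b[1],
        direction = best$direction, n_anchors = nrow(chain),
        start_a = min(chain$index_a), end_a = max(chain$index_a),
        start_b = min(chain$index_b), end_b = max(chain$index_b),
        anchors = list(chain)
      )
      pool <- pool[-best$idx, ]
    }
  }
  out <- bind_rows(blocks) %||%
    tibble(chrom_a = character(), chrom_b = character(),
           direction = character(), n_anchors = integer(),
           start_a = numeric(), end_a = numeric(),
           start_b = numeric(), end_b = numeric(), anchors = list())
  if (nrow(out) > 0L) {
    out <- out[order(out$chrom_a, out$chrom_b, out$start_a), ]
    out <- mutate(out, block_id = paste0("block", row_number()),
                  .before = 1L)
  } else {
    out <- mutate(out, block_id = character(), .before = 1L)
  }
  out
}

rank_anchors <- function(anchors) {
  need <- c("gene_a", "chrom_a", "gene_b", "chrom_b")
  if (!all(need %in% names(anchors))) {
    abort(paste0("anchors need columns: ", paste(need, collapse = ", ")))
  }
  if (!all(c("index_a", "index_b") %in% names(anchors))) {
    if (!all(c("start_a", "start_b") %in% names(anchors))) {
      abort("anchors need either index_a/index_b ranks or start_a/start_b coordinates")
    }
    anchors <- anchors |>
      group_by(.data$chrom_a) |>
      mutate(index_a = rank(.data$start_a, ties.method = "first")) |>
      ungroup() |>
      group_by(.data$chrom_b) |>
      mutate(index_b = rank(.data$start_b, ties.method = "first")) |>
      ungroup()
  }
  anchors
}

# longest gap-constrained strictly monotone chain over one chromosome pair,
# considering both directions; returns row indices into `pool` plus the
# direction, or NULL for an empty pool
best_chain <- function(pool, max_rank_gap) {
  n <- nrow(pool)
  if (n == 0L) return(NULL)
  ord <- order(pool$index_a, pool$index_b)
  ia <- pool$index_a[ord]
  ib <- pool$index_b[ord]
  run <- function(sign_b) {
    len <- rep(1L, n); pred <- rep(0L, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        da <- ia[j] - ia[i]
        db <- sign_b * (ib[j] - ib[i])
        if (da >= 1 && da <= max_rank_gap && db >= 1 && db <= max_rank_gap &&
            len[i] + 1L > len[j]) {
          len[j] <- len[i] + 1L
          pred[j] <- i
        }
      }
    }
    ends <- which(len == max(len))
    # tie-break: the chain starting at the smallest index_a
    starts <- vapply(ends, function(e) {
      while (pred[e] != 0L) e <- pred[e]
      ia[e]
    }, numeric(1))
    e <- ends[order(starts, ia[ends])][1]
    idx <- integer()
    while (e != 0L) { idx <- c(e, idx); e <- pred[e] }
    idx
  }
  fwd <- run(1); inv <- run(-1)
  if (length(fwd) >= length(inv)) {
    chosen <- fwd; direction <- "forward"
    if (length(fwd) == length(inv) && length(inv) > 0 &&
        ia[inv[1]] < ia[fwd[1]]) { chosen <- inv; direction <- "inverted" }
  } else {
    chosen <- inv; direction <- "inverted"
  }
  list(idx = ord[chosen], direction = direction)
}

#' Bin divergence values into a fixed-width histogram
#'
#' Half-open bins `[i*w, (i+1)*w)`; the modal bin is the bin with the
#' highest count, ties going to the smaller bin.
#'
#' @param values Non-negative divergence values.
#' @param bin_width Bin width.
#' @return A tibble with `bin_lo`, `bin_hi`, `count` covering the occupied
#'   range (empty interior bins included), of class `divergence_histogram`
#'   with attributes `modal_lo`/`modal_hi`.
#' @export
divergence_histogram <- function(values, bin_width = 0.01) {
  if (length(values) == 0L) abort("no values to bin")
  if (any(!is.finite(values))) abort("values must be finite")
  idx <- floor(values / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- table(factor(idx, levels = rng))
  out <- tibble(bin_lo = rng * bin_width, bin_hi = (rng + 1) * bin_width,
                count = as.integer(counts))
  modal <- which.max(out$count)  # which.max takes the first (smaller bin) on ties
  attr(out, "modal_lo") <- out$bin_lo[modal]
  attr(out, "modal_hi") <- out$bin_hi[modal]
  class(out) <- c("divergence_histogram", class(out))
  out
}

#' Modal bin of a divergence histogram
#'
#' @param hist A `divergence_histogram`.
#' @return A one-row tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
modal_bin <- function(hist) {
  hist[hist$bin_lo == attr(hist, "modal_lo"), c("bin_lo", "bin_hi", "count")]
}
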