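#' Map BAC-end query ids to BAC ids
#'
#' BAC-end alignments are named per end (e.g. `B0001_1`, `B0001_2`); the
#' physical-map membership table is keyed by BAC. The default pattern
#' strips a trailing `_1`/`_2` end suffix.
#'
#' @param query_id Character vector of BAC-end ids.
#' @param end_pattern Regular expression removed to obtain the BAC id.
#' @return Character vector of BAC ids.
#' @export
bac_end_to_bac <- function(query_id, end_pattern = "_[12]$") {
  sub(end_pattern, "", query_id)
}

# annotate hits with bac_id and contig_id; drop hits whose BAC has no
# membership row or is a singleton (logged)
resolve_bac_hits <- function(bac_hits, memberships, end_pattern = "_[12]$") {
  bac_hits$bac_id <- bac_end_to_bac(bac_hits$query_id, end_pattern)
  contig <- setNames(memberships$contig_id, memberships$bac_id)
  bac_hits$contig_id <- unname(contig[bac_hits$bac_id])
  unresolved <- is.na(bac_hits$contig_id)
  if (any(unresolved)) {
    inform(sprintf("bac links: dropped %d hit(s) from BACs in no physical contig",
                   sum(unresolved)))
  }
  bac_hits[!unresolved, ]
}

#' Remove hits belonging to sink (repeat-aggregating) physical contigs
#'
#' A sink contig links indiscriminately to scaffolds genome-wide. Hits are
#' removed for explicitly named contigs and, when `auto = TRUE`, for
#' contigs whose scaffold degree (number of distinct scaffolds hit) exceeds
#' the mean plus three standard deviations of the per-contig degree
#' distribution.
#'
#' @param bac_hits Alignment-hit tibble for BAC ends (already filtered with
#'   [filter_hits()]).
#' @param memberships BAC membership tibble ([read_physical_map()]).
#' @param explicit_ids Character vector of contig ids to drop outright.
#' @param auto Auto-detect high-degree sinks?
#' @param end_pattern See [bac_end_to_bac()].
#' @return The retained hits, annotated with `bac_id` and `contig_id`. The
#'   `sink_contigs` attribute lists the contigs removed.
#' @export
filter_sink_contigs <- function(bac_hits, memberships, explicit_ids = character(),
                                auto = TRUE, end_pattern = "_[12]$") {
  x <- resolve_bac_hits(bac_hits, memberships, end_pattern)
  sinks <- intersect(unique(x$contig_id), explicit_ids)
  if (auto && nrow(x) > 0L) {
    deg <- tapply(x$target_id, x$contig_id, function(s) length(unique(s)))
    degv <- as.vector(deg)
    # leave-one-out so an extreme sink cannot mask itself by inflating the SD
    if (length(degv) >= 3L) {
      flagged <- vapply(seq_along(degv), function(i) {
        others <- degv[-i]
        cutoff <- mean(others) + 3 * stats::sd(others)
        is.finite(cutoff) && degv[i] > cutoff
      }, logical(1))
      sinks <- union(sinks, names(deg)[flagged])
    }
  }
  if (length(sinks) > 0L) {
    inform(sprintf("bac links: filtered sink contig(s): %s",
                   paste(sort(sinks), collapse = ", ")))
  }
  out <- x[!x$contig_id %in% sinks, ]
  attr(out, "sink_contigs") <- sort(sinks)
  out
}

#' Classify scaffold-to-physical-contig links
#'
#' Per scaffold, alignments are counted per contig and the link to the
#' top contig is classified, in order: *unique* (every alignment to one
#' contig, with at least `min_total_unique` alignments), *dominant* (top
#' contig holds more than half of at least `min_total_dominant`
#' alignments), *strong* (top count at least `strong_ratio` times the
#' second-best and at least `strong_min`), else *rejected*. A tie for the
#' top contig is rejected.
#'
#' @param bac_hits Sink-filtered, threshold-filtered BAC-end hits carrying
#'   `contig_id` (see [filter_sink_contigs()]).
#' @param min_total_unique,min_total_dominant,strong_ratio,strong_min
#'   Classification thresholds.
#' @return A tibble of link calls: `scaffold_id`, `contig_id`, `n_total`,
#'   `n_to_contig`, `category`.
#' @export
classify_links <- function(bac_hits, min_total_unique = 2L,
                           min_total_dominant = 4L, strong_ratio = 2.0,
                           strong_min = 3L) {
  scaffolds <- sort(unique(bac_hits$target_id))
  out <- lapply(scaffolds, function(s) {
    counts <- table(bac_hits$contig_id[bac_hits$target_id == s])
    counts <- counts[order(-as.vector(counts), names(counts))]
    n_total <- sum(counts)
    top <- as.vector(counts[1])
    tie <- length(counts) > 1L && as.vector(counts[2]) == top
    second <- if (length(counts) > 1L) as.vector(counts[2]) else 0L
    category <- "rejected"
    if (!tie) {
      if (length(counts) == 1L && n_total >= min_total_unique) {
        category <- "unique"
      } else if (top / n_total > 0.5 && n_total >= min_total_dominant) {
        category <- "dominant"
      } else if (top >= strong_ratio * second && top >= strong_min &&
                 length(counts) > 1L) {
        category <- "strong"
      }
    }
    tibble(scaffold_id = s, contig_id = names(counts)[1],
           n_total = as.integer(n_total), n_to_contig = as.integer(top),
           category = category)
  })
  bind_rows(out) %||%
    tibble(scaffold_id = character(), contig_id = character(),
           n_total = integer(), n_to_contig = integer(), category = character())
}

#' Propagate placements to unplaced scaffolds through shared contigs
#'
#' An unplaced scaffold with an accepted link to contig *C* is placed on
#' the linkage group of a marker-placed scaffold that also links *C*,
#' inserted immediately after it in order (same `cm_key`, increasing
#' sub-rank), with orientation `?` and evidence `bac_link`. When several
#' placed scaffolds share the contig, the one with the most supporting
#' alignments anchors the newcomer (ties broken by scaffold id). Placed
#' scaffolds are never moved; neighbours disagreeing on the linkage group
#' abstain with a logged conflict.
#'
#' @param link_calls Output of [classify_links()].
#' @param marker_placements Placement tibble from the marker stage.
#' @return The additional placements (evidence `bac_link`), with columns
#'   `anchor_id` and `sub_rank` recording the insertion point.
#' @export
propagate_placement <- function(link_calls, marker_placements) {
  accepted <- link_calls[link_calls$category != "rejected", ]
  placed_ids <- marker_placements$scaffold_id
  anchors <- accepted[accepted$scaffold_id %in% placed_ids, ]
  candidates <- accepted[!accepted$scaffold_id %in% placed_ids, ]
  # a scaffold with several accepted links is considered strongest-first
  # and placed at most once
  candidates <- candidates[order(candidates$scaffold_id,
                                 -candidates$n_to_contig,
                                 candidates$contig_id), ]
  new_rows <- list()
  sub_rank <- integer()  # per-anchor counter
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (cand$scaffold_id %in% names(new_rows)) next
    nb <- anchors[anchors$contig_id == cand$contig_id, ]
    if (nrow(nb) == 0L) next
    nb_pl <- marker_placements[match(nb$scaffold_id, marker_placements$scaffold_id), ]
    lgs <- unique(nb_pl$linkage_group)
    if (length(lgs) > 1L) {
      warn(sprintf("bac links: scaffold %s not placed; contig %s neighbours disagree on linkage group (%s)",
                   cand$scaffold_id, cand$contig_id, paste(lgs, collapse = ", ")))
      next
    }
    nb <- nb[order(-nb$n_to_contig, nb$scaffold_id), ]
    anchor <- nb$scaffold_id[1]
    rank_here <- if (anchor %in% names(sub_rank)) sub_rank[[anchor]] + 1L else 1L
    sub_rank[anchor] <- rank_here
    anchor_pl <- marker_placements[marker_placements$scaffold_id == anchor, ][1, ]
    new_rows[[cand$scaffold_id]] <- tibble(
      scaffold_id = cand$scaffold_id, linkage_group = anchor_pl$linkage_group,
      cm_key = anchor_pl$cm_key, orientation = "?", evidence = "bac_link",
      split_of = NA_character_, n_support_markers = 0L,
      anchor_id = anchor, sub_rank = rank_here
    )
  }
  out <- bind_rows(new_rows) %||%
    dplyr::mutate(empty_placements(), anchor_id = character(),
                  sub_rank = integer())
  inform(sprintf("bac links: propagated %d additional placement(s)", nrow(out)))
  out
}
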