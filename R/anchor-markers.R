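#' Filter alignment hits on identity and coverage
#'
#' Keeps hits with identity and coverage strictly greater than the
#' thresholds (the retention rule is ">90% base-pair identity and >90%
#' coverage"). Input order is preserved; the reader/filter split means
#' thresholding is testable in isolation.
#'
#' @param hits A tibble of alignment hits ([read_psl()]/[read_blast6()]).
#' @param min_identity,min_coverage Strict lower bounds, as fractions.
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 0.90, min_coverage = 0.90) {
  hits[!is.na(hits$identity) & !is.na(hits$coverage) &
         hits$identity > min_identity & hits$coverage > min_coverage, ]
}

#' Merge a marker's positions from two genetic maps
#'
#' When both maps position a marker, the new position is discarded if it
#' differs from the published one by more than `max_discord_cm`; otherwise
#' the two are averaged. With a single source, that value is used.
#'
#' @param cm_published,cm_new Numeric vectors of cM positions (`NA` =
#'   absent). Recycled to a common length.
#' @param max_discord_cm Discordance threshold in cM.
#' @return Resolved cM positions.
#' @export
merge_map_positions <- function(cm_published, cm_new, max_discord_cm = 30.0) {
  n <- max(length(cm_published), length(cm_new))
  cm_published <- rep_len(cm_published, n)
  cm_new <- rep_len(cm_new, n)
  if (any(is.na(cm_published) & is.na(cm_new))) {
    abort("marker has no position in either map")
  }
  both <- !is.na(cm_published) & !is.na(cm_new)
  out <- ifelse(is.na(cm_published), cm_new, cm_published)
  discord <- both & abs(cm_published - cm_new) > max_discord_cm
  out[both & !discord] <- (cm_published[both & !discord] + cm_new[both & !discord]) / 2
  out[discord] <- cm_published[discord]
  out
}

#' Place map markers onto scaffolds from filtered alignments
#'
#' Every retained (marker, scaffold, position) alignment becomes one placed
#' marker. Markers aligning at more than one position are tagged
#' `ambiguous` and retained. Markers present in neither map are dropped
#' (count reported); markers whose two maps disagree on the linkage group
#' are kept but flagged removed with reason `discordant_unresolvable`.
#'
#' @param hits Filtered alignment hits (see [filter_hits()]).
#' @param map_published,map_new Genetic-map tibbles with columns
#'   `marker_id`, `linkage_group`, `cm` (the `source` column, if present,
#'   is ignored).
#' @param max_discord_cm Passed to [merge_map_positions()].
#' @return A tibble of placed markers with columns `marker_id`,
#'   `scaffold_id`, `scaffold_pos` (0-based), `linkage_group`,
#'   `cm_published`, `cm_new`, `cm_resolved`, `ambiguous`, `removed`,
#'   `removed_reason`. Marker ids found in no map are recorded in the
#'   `dropped_unmapped` attribute.
#' @export
place_markers <- function(hits, map_published, map_new, max_discord_cm = 30.0) {
  pub <- map_published[!duplicated(map_published$marker_id), ]
  new <- map_new[!duplicated(map_new$marker_id), ]
  lg_pub <- setNames(pub$linkage_group, pub$marker_id)
  cm_pub <- setNames(pub$cm, pub$marker_id)
  lg_new <- setNames(new$linkage_group, new$marker_id)
  cm_new <- setNames(new$cm, new$marker_id)

  in_pub <- hits$query_id %in% names(lg_pub)
  in_new <- hits$query_id %in% names(lg_new)
  dropped <- unique(hits$query_id[!in_pub & !in_new])
  if (length(dropped) > 0L) {
    inform(sprintf("place_markers: dropped %d marker(s) present in neither map",
                   length(dropped)))
  }
  x <- hits[in_pub | in_new, ]
  if (nrow(x) == 0L) {
    out <- tibble(marker_id = character(), scaffold_id = character(),
                  scaffold_pos = numeric(), linkage_group = character(),
                  cm_published = numeric(), cm_new = numeric(),
                  cm_resolved = numeric(), ambiguous = logical(),
                  removed = logical(), removed_reason = character())
    attr(out, "dropped_unmapped") <- dropped
    return(out)
  }
  mpub <- unname(lg_pub[x$query_id])
  mnew <- unname(lg_new[x$query_id])
  cpub <- unname(cm_pub[x$query_id])
  cnew <- unname(cm_new[x$query_id])
  discordant_lg <- !is.na(mpub) & !is.na(mnew) & mpub != mnew
  lg <- ifelse(is.na(mpub), mnew, mpub)
  n_hits <- table(x$query_id)
  resolved <- rep(NA_real_, nrow(x))
  ok <- !discordant_lg
  resolved[ok] <- merge_map_positions(cpub[ok], cnew[ok], max_discord_cm)
  out <- tibble(
    marker_id = x$query_id,
    scaffold_id = x$target_id,
    scaffold_pos = x$target_start,
    linkage_group = ifelse(discordant_lg, NA_character_, lg),
    cm_published = cpub,
    cm_new = cnew,
    cm_resolved = resolved,
    ambiguous = as.vector(n_hits[x$query_id]) > 1L,
    removed = discordant_lg,
    removed_reason = ifelse(discordant_lg, "discordant_unresolvable", "none")
  )
  n_rm <- sum(discordant_lg)
  if (n_rm > 0L) {
    inform(sprintf("place_markers: removed %d placement(s) with irreconcilable linkage groups", n_rm))
  }
  attr(out, "dropped_unmapped") <- dropped
  out
}

#' Resolve the linkage group of one scaffold from its placed markers
#'
#' Votes over linkage groups using unambiguous markers when any exist;
#' multi-position (ambiguous) markers are retained but may only decide a
#' linkage group when at least two of them agree. A single marker
#' dissenting against two or more agreeing markers is removed. Two
#' coordinate-separable groups of two or more markers each yield a split
#' decision at the midpoint between the innermost markers; interleaved
#' groups, 1-vs-1 conflicts and empty inputs are unplaceable.
#'
#' @param markers Placed markers of a single scaffold (non-removed rows
#'   with `cm_resolved` set).
#' @param min_ambiguous_agree Minimum count of agreeing ambiguous markers
#'   needed when no unambiguous marker is available.
#' @return A list with `status` (`"placed"`, `"split"` or
#'   `"unplaceable"`), `placement` (one-row tibble or `NULL`), `split`
#'   (one-row tibble or `NULL`), `removed_marker_ids` (dissenters), and
#'   `interleaved` flag.
#' @export
resolve_scaffold_lg <- function(markers, min_ambiguous_agree = 2L) {
  unplaceable <- function(interleaved = FALSE) {
    list(status = "unplaceable", placement = NULL, split = NULL,
         removed_marker_ids = character(), interleaved = interleaved)
  }
  markers <- markers[!markers$removed & !is.na(markers$cm_resolved), ]
  if (nrow(markers) == 0L) return(unplaceable())
  scaffold_id <- markers$scaffold_id[1]

  voters <- markers[!markers$ambiguous, ]
  ambiguous_only <- nrow(voters) == 0L
  if (ambiguous_only) voters <- markers

  counts <- sort(table(voters$linkage_group), decreasing = TRUE)
  counts <- counts[order(-as.vector(counts), names(counts))]
  removed_ids <- character()

  # single-dissenter rule: groups of one against a majority of >= 2
  if (length(counts) > 1L && max(counts) >= 2L && any(counts == 1L)) {
    dissent_lgs <- names(counts)[counts == 1L]
    removed_ids <- voters$marker_id[voters$linkage_group %in% dissent_lgs]
    voters <- voters[!voters$linkage_group %in% dissent_lgs, ]
    counts <- counts[!names(counts) %in% dissent_lgs]
  }

  placement_for <- function(lg) {
    support <- markers[markers$linkage_group == lg &
                         !markers$marker_id %in% removed_ids, ]
    tibble(scaffold_id = scaffold_id, linkage_group = lg,
           cm_key = mean(support$cm_resolved), orientation = "?",
           evidence = "marker", split_of = NA_character_,
           n_support_markers = nrow(support))
  }
  done <- function(lg) {
    list(status = "placed", placement = placement_for(lg), split = NULL,
         removed_marker_ids = removed_ids, interleaved = FALSE)
  }

  if (length(counts) == 1L) {
    if (ambiguous_only && counts[[1]] < min_ambiguous_agree) return(unplaceable())
    return(done(names(counts)[1]))
  }
  if (max(counts) >= 2L) {
    # after dissenter removal, every remaining group has >= 2 markers:
    # look for a two-segment coordinate partition over some pair of groups
    eligible <- names(counts)[counts >= 2L]
    best <- NULL
    for (i in seq_len(length(eligible) - 1L)) {
      for (j in seq(i + 1L, length(eligible))) {
        part <- best_two_segment_partition(voters, eligible[c(i, j)])
        if (!is.null(part) &&
            (is.null(best) || part$score < best$score ||
               (part$score == best$score && part$min_maj > best$min_maj))) {
          best <- part
        }
      }
    }
    if (is.null(best)) {
      return(list(status = "unplaceable", placement = NULL, split = NULL,
                  removed_marker_ids = removed_ids, interleaved = TRUE))
    }
    removed_ids <- c(removed_ids, best$violators)
    split <- tibble(scaffold_id = scaffold_id, split_pos = best$split_pos,
                    left_lg = best$left_lg, right_lg = best$right_lg,
                    interleaved = FALSE)
    return(list(status = "split", placement = NULL, split = split,
                removed_marker_ids = removed_ids, interleaved = FALSE))
  }
  # only singleton groups remain (e.g. 1-vs-1): abstain
  list(status = "unplaceable", placement = NULL, split = NULL,
       removed_marker_ids = removed_ids, interleaved = FALSE)
}

# Candidate linkage-group pair (lgs): find the two-segment coordinate
# partition minimizing cross-assigned markers (markers of any other group
# count as violators on their side). The split is accepted when each
# segment holds a majority of >= 2 markers of its own linkage group and
# the violators are a strict minority on their side (the single-dissenter
# principle applied per side); those markers are removed as dissenters.
# Returns NULL (interleaved) otherwise. The split position is the midpoint
# between the innermost majority markers of the two segments.
best_two_segment_partition <- function(voters, lgs) {
  v <- voters[order(voters$scaffold_pos, voters$marker_id), ]
  n <- nrow(v)
  is_a <- v$linkage_group == lgs[1]
  is_b <- v$linkage_group == lgs[2]
  best <- NULL
  for (cut in 1:(n - 1L)) {         # cut after marker `cut`
    left <- seq_len(cut)
    right <- seq(cut + 1L, n)
    for (ord in 1:2) {
      a_left <- ord == 1L
      viol_left <- if (a_left) sum(!is_a[left]) else sum(!is_b[left])
      viol_right <- if (a_left) sum(!is_b[right]) else sum(!is_a[right])
      maj_left <- length(left) - viol_left
      maj_right <- length(right) - viol_right
      score <- viol_left + viol_right
      # ties on violation count go to the partition with the strongest
      # support on its weaker side
      min_maj <- min(maj_left, maj_right)
      if (maj_left >= 2L && maj_right >= 2L &&
          viol_left < maj_left && viol_right < maj_right &&
          (is.null(best) || score < best$score ||
             (score == best$score && min_maj > best$min_maj))) {
        left_lg <- if (a_left) lgs[1] else lgs[2]
        maj_l <- left[(v$linkage_group[left] == left_lg)]
        right_lg <- if (a_left) lgs[2] else lgs[1]
        maj_r <- right[(v$linkage_group[right] == right_lg)]
        best <- list(
          score = score, min_maj = min_maj,
          left_lg = left_lg, right_lg = right_lg,
          split_pos = (max(v$scaffold_pos[maj_l]) +
                         min(v$scaffold_pos[maj_r])) / 2,
          violators = v$marker_id[c(left[v$linkage_group[left] != left_lg],
                                    right[v$linkage_group[right] != right_lg])]
        )
      }
    }
  }
  best
}

#' Resolve all scaffolds and collect placements, splits and removals
#'
#' @param placed Placed-marker tibble from [place_markers()].
#' @param min_ambiguous_agree See [resolve_scaffold_lg()].
#' @return A list with `placements`, `splits` and the updated `markers`
#'   tibble (dissenters flagged removed).
#' @export
resolve_scaffolds <- function(placed, min_ambiguous_agree = 2L) {
  scaffolds <- sort(unique(placed$scaffold_id))
  placements <- list(); splits <- list()
  for (s in scaffolds) {
    res <- resolve_scaffold_lg(placed[placed$scaffold_id == s, ],
                               min_ambiguous_agree)
    if (length(res$removed_marker_ids) > 0L) {
      sel <- placed$scaffold_id == s & placed$marker_id %in% res$removed_marker_ids
      placed$removed[sel] <- TRUE
      placed$removed_reason[sel] <- "dissenter"
    }
    if (res$status == "placed") placements[[s]] <- res$placement
    if (res$status == "split") splits[[s]] <- res$split
  }
  list(
    placements = bind_rows(placements) %||% empty_placements(),
    splits = if (length(splits)) bind_rows(splits) else
      tibble(scaffold_id = character(), split_pos = numeric(),
             left_lg = character(), right_lg = character(),
             interleaved = logical()),
    markers = placed
  )
}

empty_placements <- function() {
  tibble(scaffold_id = character(), linkage_group = character(),
         cm_key = numeric(), orientation = character(),
         evidence = character(), split_of = NA_character_[0],
         n_support_markers = integer())
}

#' Split chimeric scaffolds and reassign their markers
#'
#' Each split scaffold `<id>` is replaced by `<id>_1` (left of the split)
#' and `<id>_2`; marker coordinates on the right child are shifted by the
#' split position.
#'
#' @param sequences A named [Biostrings::DNAStringSet] of scaffolds.
#' @param splits Split decisions ([resolve_scaffolds()]).
#' @param markers Optional placed-marker tibble to reassign.
#' @return A list with the new `sequences`, updated `markers` and a
#'   `children` tibble mapping child ids to parents.
#' @export
apply_splits <- function(sequences, splits, markers = NULL) {
  children <- list()
  for (i in seq_len(nrow(splits))) {
    sp <- splits[i, ]
    id <- sp$scaffold_id
    if (!id %in% names(sequences)) {
      abort(sprintf("split scaffold %s has no sequence", id))
    }
    len <- length(sequences[[id]])
    pos <- sp$split_pos
    if (pos <= 0 || pos >= len) {
      abort(sprintf("split position %s outside (0, %d) for scaffold %s",
                    format(pos), len, id))
    }
    cut <- floor(pos)
    left <- Biostrings::subseq(sequences[[id]], 1L, cut)
    right <- Biostrings::subseq(sequences[[id]], cut + 1L, len)
    sequences <- sequences[names(sequences) != id]
    add <- Biostrings::DNAStringSet(list(left, right))
    names(add) <- paste0(id, c("_1", "_2"))
    sequences <- c(sequences, add)
    children[[id]] <- tibble(parent_id = id,
                             child_id = paste0(id, c("_1", "_2")),
                             child_start = c(0, cut), child_end = c(cut, len))
    if (!is.null(markers)) {
      on_parent <- markers$scaffold_id == id
      right_side <- on_parent & markers$scaffold_pos >= cut
      markers$scaffold_id[on_parent & !right_side] <- paste0(id, "_1")
      markers$scaffold_id[right_side] <- paste0(id, "_2")
      markers$scaffold_pos[right_side] <- markers$scaffold_pos[right_side] - cut
    }
  }
  list(sequences = sequences, markers = markers,
       children = if (length(children)) bind_rows(children) else
         tibble(parent_id = character(), child_id = character(),
                child_start = numeric(), child_end = numeric()))
}

#' Anchor scaffolds to linkage groups from marker alignments
#'
#' Full marker stage: threshold filtering, placement against both maps,
#' per-scaffold linkage-group resolution with dissenter removal, chimera
#' splitting (when sequences are supplied) and re-resolution of the split
#' children.
#'
#' @param hits Unfiltered alignment hits.
#' @param map_published,map_new Genetic-map tibbles.
#' @param sequences Optional scaffold [Biostrings::DNAStringSet]; required
#'   for splits to be applied.
#' @param min_identity,min_coverage,max_discord_cm Thresholds.
#' @return An object of class `anchor_result`: a list with `placements`,
#'   `splits`, `markers`, `sequences` and bookkeeping `counts`.
#' @export
anchor_scaffolds <- function(hits, map_published, map_new, sequences = NULL,
                             min_identity = 0.90, min_coverage = 0.90,
                             max_discord_cm = 30.0) {
  kept <- filter_hits(hits, min_identity, min_coverage)
  inform(sprintf("anchor: retained %d of %d alignment(s)", nrow(kept), nrow(hits)))
  placed <- place_markers(kept, map_published, map_new, max_discord_cm)
  res <- resolve_scaffolds(placed)
  placements <- res$placements
  splits <- res$splits
  markers <- res$markers
  if (nrow(splits) > 0L && !is.null(sequences)) {
    ap <- apply_splits(sequences, splits, markers)
    sequences <- ap$sequences
    markers <- ap$markers
    child_ids <- ap$children$child_id
    res2 <- resolve_scaffolds(markers[markers$scaffold_id %in% child_ids, ])
    if (nrow(res2$placements) > 0L) {
      res2$placements$split_of <-
        ap$children$parent_id[match(res2$placements$scaffold_id,
                                    ap$children$child_id)]
      placements <- bind_rows(placements, res2$placements)
    }
    markers[markers$scaffold_id %in% child_ids, ] <- res2$markers
  }
  inform(sprintf("anchor: placed %d scaffold(s), split %d, removed %d marker placement(s)",
                 nrow(placements), nrow(splits), sum(markers$removed)))
  structure(
    list(placements = placements, splits = splits, markers = markers,
         sequences = sequences,
         counts = tibble(
           n_hits = nrow(hits), n_hits_retained = nrow(kept),
           n_markers_placed = length(unique(markers$marker_id[!markers$removed])),
           n_markers_removed = length(unique(markers$marker_id[markers$removed])),
           n_markers_dropped = length(attr(placed, "dropped_unmapped")),
           n_scaffolds_placed = nrow(placements), n_scaffolds_split = nrow(splits)
         )),
    class = "anchor_result"
  )
}

#' @export
print.anchor_result <- function(x, ...) {
  cat("<anchor_result>\n")
  print(x$counts)
  invisible(x)
}

#' Tidy an anchor result into its placement table
#'
#' @param x An `anchor_result`.
#' @param ... Unused.
#' @return The placements tibble.
#' @method tidy anchor_result
#' @export
tidy.anchor_result <- function(x, ...) as_tibble(x$placements)

#' One-row summary of an anchoring run
#'
#' @param x An `anchor_result`.
#' @param ... Unused.
#' @return A one-row tibble of bookkeeping counts.
#' @method glance anchor_result
#' @export
glance.anchor_result <- function(x, ...) x$counts
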