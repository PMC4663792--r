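#' Orient a scaffold from the cM gradient of its markers
#'
#' The orientation is the sign of the Kendall-type statistic
#' (concordant minus discordant pairs) between base position on the
#' scaffold and resolved cM: positive gives `+`, negative `-`, zero or
#' fewer than two distinct-cM markers `?`.
#'
#' @param markers Placed markers of one scaffold (columns `scaffold_pos`,
#'   `cm_resolved`).
#' @return `"+"`, `"-"` or `"?"`.
#' @export
orient_scaffold <- function(markers) {
  x <- markers$scaffold_pos
  y <- markers$cm_resolved
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || length(unique(y)) < 2L) return("?")
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    for (j in seq(i + 1L, length(x))) {
      s <- s + sign((x[j] - x[i]) * (y[j] - y[i]))
    }
  }
  if (s > 0) "+" else if (s < 0) "-" else "?"
}

#' Fill in orientations for marker-placed scaffolds
#'
#' @param placements Placement tibble.
#' @param markers Placed-marker tibble (non-removed markers are used).
#' @return `placements` with `orientation` set from [orient_scaffold()]
#'   for marker-evidence rows; `bac_link` rows stay `?`.
#' @export
orient_placements <- function(placements, markers) {
  live <- markers[!markers$removed, ]
  for (i in seq_len(nrow(placements))) {
    if (!identical(placements$evidence[i], "marker")) next
    m <- live[live$scaffold_id == placements$scaffold_id[i] &
                live$linkage_group == placements$linkage_group[i], ]
    placements$orientation[i] <- orient_scaffold(m)
  }
  placements
}

#' Order placed scaffolds within each linkage group
#'
#' Marker-placed scaffolds are sorted by (`cm_key`, scaffold id);
#' BAC-linked scaffolds are inserted immediately after their anchor in
#' sub-rank order. The result is deterministic for identical inputs.
#'
#' @param placements Placement tibble (marker and/or `bac_link` evidence;
#'   `bac_link` rows carry `anchor_id` and `sub_rank`).
#' @return The placements sorted into emission order with an added
#'   `order_index` column (1-based within each linkage group).
#' @export
order_scaffolds <- function(placements) {
  if (nrow(placements) == 0L) {
    return(mutate(placements, order_index = integer()))
  }
  if (!"anchor_id" %in% names(placements)) placements$anchor_id <- NA_character_
  if (!"sub_rank" %in% names(placements)) placements$sub_rank <- NA_integer_
  out <- list()
  for (lg in sort(unique(placements$linkage_group))) {
    p <- placements[placements$linkage_group == lg, ]
    base <- p[p$evidence != "bac_link", ]
    base <- base[order(base$cm_key, base$scaffold_id), ]
    prop <- p[p$evidence == "bac_link", ]
    rows <- list()
    for (i in seq_len(nrow(base))) {
      rows[[length(rows) + 1L]] <- base[i, ]
      att <- prop[!is.na(prop$anchor_id) & prop$anchor_id == base$scaffold_id[i], ]
      if (nrow(att) > 0L) {
        rows[[length(rows) + 1L]] <- att[order(att$sub_rank, att$scaffold_id), ]
      }
    }
    orphan <- prop[is.na(prop$anchor_id) |
                     !prop$anchor_id %in% base$scaffold_id, ]
    if (nrow(orphan) > 0L) {
      rows[[length(rows) + 1L]] <- orphan[order(orphan$cm_key, orphan$scaffold_id), ]
    }
    p_ord <- bind_rows(rows)
    p_ord$order_index <- seq_len(nrow(p_ord))
    out[[lg]] <- p_ord
  }
  bind_rows(out)
}

#' Build gap-padded pseudomolecules from ordered placements
#'
#' Concatenates each linkage group's scaffolds in order, reverse-
#' complementing `-` components and treating `?` as `+` in sequence while
#' keeping `?` in the AGP, with a fixed-length run of `N` between adjacent
#' scaffolds (one gap per join).
#'
#' @param placements Ordered placements ([order_scaffolds()]).
#' @param sequences Named [Biostrings::DNAStringSet] holding every placed
#'   scaffold.
#' @param gap_length Gap size in bp between adjacent scaffolds.
#' @param name_by Optional named character vector mapping linkage group to
#'   pseudomolecule name; defaults to the linkage-group id itself.
#' @return An object of class `pseudomolecule_set`: list with `sequences`
#'   (one entry per pseudomolecule), `agp`, `objects` summary tibble and
#'   `unplaced` (ids of scaffolds not in any object).
#' @export
build_pseudomolecules <- function(placements, sequences, gap_length = 10000,
                                  name_by = NULL) {
  if (!"order_index" %in% names(placements)) {
    placements <- order_scaffolds(placements)
  }
  missing_seq <- setdiff(placements$scaffold_id, names(sequences))
  if (length(missing_seq) > 0L) {
    abort(paste0("no sequence for placed scaffold(s): ",
                 paste(missing_seq, collapse = ", ")))
  }
  lgs <- sort(unique(placements$linkage_group))
  agp_rows <- list()
  seqs <- character()
  objects <- list()
  for (lg in lgs) {
    obj <- if (!is.null(name_by)) unname(name_by[lg]) else lg
    p <- placements[placements$linkage_group == lg, ]
    p <- p[order(p$order_index), ]
    pieces <- character(2L * nrow(p) - 1L)
    at <- 0  # 0-based cursor
    part <- 0L
    for (i in seq_len(nrow(p))) {
      sid <- p$scaffold_id[i]
      if (i > 1L) {
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- tibble(
          object_id = obj, object_start = at + 1, object_end = at + gap_length,
          part_number = part, component_type = "N", component_id = NA_character_,
          component_start = NA_real_, component_end = NA_real_,
          orientation = NA_character_, gap_length = gap_length,
          gap_type = "scaffold", linkage = "yes", evidence = "map"
        )
        pieces[2L * i - 2L] <- strrep("N", gap_length)
        at <- at + gap_length
      }
      s <- as.character(sequences[[sid]])
      len <- nchar(s)
      ori <- p$orientation[i]
      pieces[2L * i - 1L] <- if (identical(ori, "-")) revcomp(s) else s
      part <- part + 1L
      agp_rows[[length(agp_rows) + 1L]] <- tibble(
        object_id = obj, object_start = at + 1, object_end = at + len,
        part_number = part, component_type = "W", component_id = sid,
        component_start = 1, component_end = len, orientation = ori,
        gap_length = NA_real_, gap_type = NA_character_,
        linkage = NA_character_, evidence = NA_character_
      )
      at <- at + len
    }
    seqs[obj] <- paste(pieces, collapse = "")
    objects[[obj]] <- tibble(object_id = obj, linkage_group = lg,
                             n_scaffolds = nrow(p), total_length = at)
  }
  agp <- bind_rows(agp_rows)
  validate_agp(agp)
  pm_seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(identical(
    as.numeric(Biostrings::width(pm_seqs)),
    as.numeric(tapply(agp$object_end, agp$object_id, max)[names(pm_seqs)])
  ))
  structure(
    list(sequences = pm_seqs, agp = agp, objects = bind_rows(objects),
         unplaced = setdiff(names(sequences), placements$scaffold_id),
         placements = placements),
    class = "pseudomolecule_set"
  )
}

#' @export
print.pseudomolecule_set <- function(x, ...) {
  cat(sprintf("<pseudomolecule_set> %d object(s), %d unplaced scaffold(s)\n",
              nrow(x$objects), length(x$unplaced)))
  print(x$objects)
  invisible(x)
}

#' Tidy a pseudomolecule set into its AGP table
#'
#' @param x A `pseudomolecule_set`.
#' @param ... Unused.
#' @return The AGP tibble.
#' @method tidy pseudomolecule_set
#' @export
tidy.pseudomolecule_set <- function(x, ...) x$agp

#' One-row summary of a pseudomolecule set
#'
#' @param x A `pseudomolecule_set`.
#' @param ... Unused.
#' @return A one-row tibble: object count, anchored length, unplaced count.
#' @method glance pseudomolecule_set
#' @export
glance.pseudomolecule_set <- function(x, ...) {
  tibble(n_objects = nrow(x$objects),
         anchored_length = sum(x$objects$total_length),
         n_scaffolds_anchored = sum(x$objects$n_scaffolds),
         n_unplaced = length(x$unplaced))
}

#' Write a pseudomolecule set to FASTA and AGP
#'
#' @param pm A `pseudomolecule_set`.
#' @param prefix Output path prefix; writes `<prefix>.fa`, `<prefix>.agp`
#'   and `<prefix>.unplaced.fa`.
#' @param scaffold_sequences The full scaffold set, used for the unplaced
#'   output; omit to skip it.
#' @return Invisibly, the paths written.
#' @export
write_pseudomolecules <- function(pm, prefix, scaffold_sequences = NULL) {
  paths <- c(fa = paste0(prefix, ".fa"), agp = paste0(prefix, ".agp"))
  write_fasta(pm$sequences, paths["fa"])
  write_agp(pm$agp, paths["agp"])
  if (!is.null(scaffold_sequences) && length(pm$unplaced) > 0L) {
    paths["unplaced"] <- paste0(prefix, ".unplaced.fa")
    write_fasta(scaffold_sequences[pm$unplaced], paths["unplaced"])
  }
  invisible(paths)
}
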