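agp_cols <- c("object_id", "object_start", "object_end", "part_number",
              "component_type", "component_id", "component_start",
              "component_end", "orientation", "gap_length", "gap_type",
              "linkage", "evidence")

#' Validate an AGP tibble
#'
#' Checks the structural invariants of AGP v2.1: within each object, rows
#' are contiguous and non-overlapping, part numbers increment by one, and
#' the object span of a `W` row equals its component span.
#'
#' @param agp An AGP tibble as produced by [build_pseudomolecules()] or
#'   [read_agp()].
#' @return `agp`, invisibly, or an error.
#' @export
validate_agp <- function(agp) {
  if (!all(agp_cols %in% names(agp))) {
    abort(paste0("AGP tibble missing columns: ",
                 paste(setdiff(agp_cols, names(agp)), collapse = ", ")))
  }
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, ]
    rows <- rows[order(rows$part_number), ]
    if (!all(rows$part_number == seq_len(nrow(rows)))) {
      abort(sprintf("AGP object %s: part numbers are not 1..n", obj))
    }
    if (any(rows$object_start > rows$object_end)) {
      abort(sprintf("AGP object %s: object_start > object_end", obj))
    }
    if (nrow(rows) > 1L) {
      gaps <- rows$object_start[-1] - rows$object_end[-nrow(rows)]
      if (any(gaps < 1)) {
        abort(sprintf("AGP object %s: overlapping rows", obj))
      }
      if (any(gaps > 1)) {
        abort(sprintf("AGP object %s: non-contiguous rows", obj))
      }
    }
    if (rows$object_start[1] != 1) {
      abort(sprintf("AGP object %s: does not start at 1", obj))
    }
    w <- rows$component_type == "W"
    span_obj <- rows$object_end - rows$object_start + 1
    if (any(w & (rows$component_end - rows$component_start + 1) != span_obj)) {
      abort(sprintf("AGP object %s: W row span mismatch", obj))
    }
    if (any(rows$gap_length[!w] != span_obj[!w])) {
      abort(sprintf("AGP object %s: N row gap_length mismatch", obj))
    }
  }
  invisible(agp)
}

#' Write an AGP v2.1 file
#'
#' Gap rows are emitted as component type `N` with gap type `scaffold`,
#' linkage `yes` and linkage evidence `map`; scaffold rows may carry
#' orientation `+`, `-` or `?`. Coordinates are 1-based inclusive. The
#' tibble is validated before anything is written.
#'
#' @param agp An AGP tibble (see [validate_agp()] for the column contract).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  w <- agp$component_type == "W"
  col6 <- ifelse(w, agp$component_id, format_int(agp$gap_length))
  col7 <- ifelse(w, format_int(agp$component_start), agp$gap_type)
  col8 <- ifelse(w, format_int(agp$component_end), agp$linkage)
  col9 <- ifelse(w, agp$orientation, agp$evidence)
  body <- paste(agp$object_id, format_int(agp$object_start),
                format_int(agp$object_end), format_int(agp$part_number),
                agp$component_type, col6, col7, col8, col9, sep = "\t")
  readr::write_lines(c("##agp-version\t2.1", body), path)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file.
#' @return An AGP tibble; inverse of [write_agp()] on valid files.
#' @export
read_agp <- function(path) {
  lines <- sub("\r$", "", readr::read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(object_id = character(), object_start = numeric(),
                  object_end = numeric(), part_number = integer(),
                  component_type = character(), component_id = character(),
                  component_start = numeric(), component_end = numeric(),
                  orientation = character(), gap_length = numeric(),
                  gap_type = character(), linkage = character(),
                  evidence = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(sprintf("AGP parse error: expected 9 columns, found %d", nf[nf != 9L][1]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  w <- m[, 5] == "W"
  agp <- tibble(
    object_id = m[, 1],
    object_start = as.numeric(m[, 2]),
    object_end = as.numeric(m[, 3]),
    part_number = as.integer(m[, 4]),
    component_type = m[, 5],
    component_id = ifelse(w, m[, 6], NA_character_),
    component_start = ifelse(w, suppressWarnings(as.numeric(m[, 7])), NA_real_),
    component_end = ifelse(w, suppressWarnings(as.numeric(m[, 8])), NA_real_),
    orientation = ifelse(w, m[, 9], NA_character_),
    gap_length = ifelse(w, NA_real_, suppressWarnings(as.numeric(m[, 6]))),
    gap_type = ifelse(w, NA_character_, m[, 7]),
    linkage = ifelse(w, NA_character_, m[, 8]),
    evidence = ifelse(w, NA_character_, m[, 9])
  )
  validate_agp(agp)
  agp
}

#' Lift a scaffold coordinate onto its pseudomolecule
#'
#' Maps a 0-based scaffold position through an AGP onto the 0-based
#' position in the assembled object. Orientation `?` components are laid
#' out forward, matching sequence emission.
#'
#' @param agp An AGP tibble.
#' @param component_id Scaffold (component) id.
#' @param pos 0-based position(s) on the scaffold.
#' @return A tibble with columns `object_id` and `object_pos` (0-based).
#' @export
agp_lift <- function(agp, component_id, pos) {
  row <- agp[agp$component_type == "W" & agp$component_id == component_id, ]
  if (nrow(row) != 1L) {
    abort(sprintf("component %s appears %d times in AGP", component_id, nrow(row)))
  }
  cs0 <- row$component_start - 1
  if (any(pos < cs0 | pos >= row$component_end)) {
    abort("position outside component span")
  }
  os0 <- row$object_start - 1
  obj_pos <- if (identical(row$orientation, "-")) {
    row$object_end - 1 - (pos - cs0)
  } else {
    os0 + (pos - cs0)
  }
  tibble(object_id = row$object_id, object_pos = obj_pos)
}

#' Map a pseudomolecule coordinate back to its scaffold
#'
#' Inverse of [agp_lift()] for positions that fall inside a `W` component.
#'
#' @param agp An AGP tibble.
#' @param object_id Pseudomolecule id.
#' @param pos 0-based position(s) on the object.
#' @return A tibble with columns `component_id` and `component_pos`
#'   (0-based); positions inside gaps yield `NA`.
#' @export
agp_unlift <- function(agp, object_id, pos) {
  rows <- agp[agp$object_id == object_id & agp$component_type == "W", ]
  comp <- rep(NA_character_, length(pos))
  cpos <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    inside <- pos >= r$object_start - 1 & pos < r$object_end
    if (!any(inside)) next
    comp[inside] <- r$component_id
    cpos[inside] <- if (identical(r$orientation, "-")) {
      (r$component_start - 1) + (r$object_end - 1 - pos[inside])
    } else {
      (r$component_start - 1) + (pos[inside] - (r$object_start - 1))
    }
  }
  tibble(component_id = comp, component_pos = cpos)
}
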