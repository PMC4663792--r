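#' Read a genetic-map table
#'
#' TSV with columns `marker_id`, `linkage_group`, `cm`, `source`; `source`
#' distinguishes the previously published map from the newly built one.
#'
#' @param path Path to a TSV file.
#' @return A tibble of genetic-map records.
#' @export
read_genetic_map <- function(path) {
  x <- read_tsv_checked(path, c("marker_id", "linkage_group", "cm", "source"),
                        readr::cols(marker_id = "c", linkage_group = "c",
                                    cm = "d", source = "c"))
  if (any(!x$source %in% c("published", "new"))) {
    abort("source must be 'published' or 'new'")
  }
  if (anyDuplicated(x[c("marker_id", "source")])) {
    abort("duplicate (marker_id, source) in genetic map")
  }
  if (any(!is.finite(x$cm)) || any(x$cm < 0)) {
    abort("cm positions must be finite and >= 0")
  }
  x
}

#' Read a BAC-to-physical-contig membership table
#'
#' TSV with columns `bac_id`, `contig_id`; an empty `contig_id` marks a
#' singleton BAC (assembled into no contig).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `bac_id`, `contig_id`, `singleton`.
#' @export
read_physical_map <- function(path) {
  x <- read_tsv_checked(path, c("bac_id", "contig_id"),
                        readr::cols(bac_id = "c", contig_id = "c"))
  if (anyDuplicated(x$bac_id)) abort("a BAC may belong to at most one contig")
  x$singleton <- is.na(x$contig_id) | !nzchar(x$contig_id)
  x$contig_id[x$singleton] <- NA_character_
  x
}

#' Read an allele-depth matrix
#'
#' TSV whose first four columns are `chrom`, `pos` (1-based), `ref`, `alt`,
#' followed by one column per individual holding `"refDepth,altDepth"`.
#'
#' @param path Path to a TSV file.
#' @return A `genotype_matrix` object (see [genotype_matrix()]).
#' @export
read_depth_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  fixed <- c("chrom", "pos", "ref", "alt")
  if (!identical(names(x)[1:4], fixed)) {
    abort(paste0("depth matrix must start with columns ",
                 paste(fixed, collapse = ", ")))
  }
  inds <- names(x)[-(1:4)]
  if (length(inds) == 0L) abort("depth matrix has no individual columns")
  sites <- tibble(chrom = x$chrom, pos = as.numeric(x$pos),
                  ref = x$ref, alt = x$alt)
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    abort("duplicate (chrom, pos) sites in depth matrix")
  }
  parse_pair <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    if (any(lengths(parts) != 2L)) abort("depth cells must be 'ref,alt'")
    matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  }
  pairs <- lapply(inds, function(i) parse_pair(x[[i]]))
  ref_depth <- vapply(pairs, function(p) p[, 1], numeric(nrow(sites)))
  alt_depth <- vapply(pairs, function(p) p[, 2], numeric(nrow(sites)))
  if (nrow(sites) == 1L) {
    ref_depth <- matrix(ref_depth, nrow = 1L)
    alt_depth <- matrix(alt_depth, nrow = 1L)
  }
  dimnames(ref_depth) <- dimnames(alt_depth) <- list(NULL, inds)
  genotype_matrix(sites, ref_depth, alt_depth)
}

#' Construct a genotype matrix from sites and allele depths
#'
#' The container used by the genotype-calling and LD functions: a site
#' table plus sites-by-individuals read-depth matrices for the reference
#' and alternate allele, and (once [call_genotypes()] has run) an
#' alt-allele dosage matrix with values 0, 1, 2 or `NA`.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param ref_depth,alt_depth Numeric matrices, sites x individuals.
#' @param genotype Optional dosage matrix of the same shape.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, ref_depth, alt_depth, genotype = NULL) {
  if (any(ref_depth < 0) || any(alt_depth < 0)) abort("negative read depth")
  if (!identical(dim(ref_depth), dim(alt_depth))) {
    abort("ref and alt depth matrices must have identical shape")
  }
  if (nrow(ref_depth) != nrow(sites)) {
    abort("depth matrices must have one row per site")
  }
  structure(
    list(sites = as_tibble(sites), ref_depth = ref_depth,
         alt_depth = alt_depth, genotype = genotype),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d individuals (%s)\n",
              nrow(x$sites), ncol(x$ref_depth),
              if (is.null(x$genotype)) "uncalled" else "called"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$ref_depth)

#' Write an allele-depth matrix to TSV
#'
#' Inverse of [read_depth_matrix()].
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_matrix <- function(gm, path) {
  out <- gm$sites[, c("chrom", "pos", "ref", "alt")]
  for (j in seq_len(ncol(gm$ref_depth))) {
    out[[colnames(gm$ref_depth)[j]]] <-
      paste0(format_int(gm$ref_depth[, j]), ",", format_int(gm$alt_depth[, j]))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Tidy a genotype matrix into long format
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return A long tibble with one row per site x individual.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  inds <- colnames(x$ref_depth)
  n_site <- nrow(x$sites)
  out <- tibble(
    chrom = rep(x$sites$chrom, times = length(inds)),
    pos = rep(x$sites$pos, times = length(inds)),
    individual = rep(inds, each = n_site),
    ref_depth = as.vector(x$ref_depth),
    alt_depth = as.vector(x$alt_depth)
  )
  if (!is.null(x$genotype)) out$genotype <- as.vector(x$genotype)
  out
}
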