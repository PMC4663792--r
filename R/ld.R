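#' Call genotypes from allele depths
#'
#' Depth-based calling for genotyping-by-sequencing data: an
#' individual-site needs at least `min_total` reads to be called at all;
#' a heterozygote additionally needs at least `min_minor` reads of the
#' minor allele. A site-individual passing the total-depth rule but with
#' a single minor-allele read is, by default, called homozygous for the
#' major allele (the read is treated as a sequencing error);
#' `single_minor = "missing"` leaves it uncalled instead.
#'
#' @param gm A `genotype_matrix`.
#' @param min_total Minimum total reads per individual-site.
#' @param min_minor Minimum minor-allele reads for a heterozygous call.
#' @param single_minor What to do when minor-allele depth is positive but
#'   below `min_minor`: call the major homozygote (`"hom"`) or leave
#'   missing (`"missing"`).
#' @return The `genotype_matrix` with its `genotype` dosage matrix filled
#'   (alt-allele dosage: 0, 1, 2 or `NA`).
#' @export
call_genotypes <- function(gm, min_total = 10L, min_minor = 2L,
                           single_minor = c("hom", "missing")) {
  single_minor <- match.arg(single_minor)
  r <- gm$ref_depth; a <- gm$alt_depth
  if (any(r < 0) || any(a < 0)) abort("negative read depth")
  total <- r + a
  minor <- pmin(r, a)
  g <- matrix(NA_real_, nrow = nrow(r), ncol = ncol(r),
              dimnames = dimnames(r))
  callable <- total >= min_total
  het <- callable & minor >= min_minor
  g[het] <- 1
  hom <- callable & !het
  if (single_minor == "missing") hom <- hom & minor == 0
  g[hom & a > r] <- 2
  g[hom & a <= r] <- 0
  gm$genotype <- g
  gm
}

#' Filter SNP sites on missingness and minor allele frequency
#'
#' A site is kept iff its missing fraction is at most `max_missing` and
#' its minor allele frequency (computed from called dosages) is at least
#' `min_maf` — i.e. removal is strict (`> max_missing`, `< min_maf`).
#'
#' @param gm A called `genotype_matrix` ([call_genotypes()] is applied
#'   with defaults if not yet called).
#' @param max_missing Maximum tolerated missing fraction.
#' @param min_maf Minimum minor allele frequency.
#' @return The `genotype_matrix` restricted to surviving sites.
#' @export
filter_sites <- function(gm, max_missing = 0.20, min_maf = 0.05) {
  if (is.null(gm$genotype)) gm <- call_genotypes(gm)
  g <- gm$genotype
  n_ind <- ncol(g)
  missing_frac <- rowSums(is.na(g)) / n_ind
  n_called <- rowSums(!is.na(g))
  p_alt <- rowSums(g, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- missing_frac <= max_missing & !is.na(maf) & maf >= min_maf
  genotype_matrix(gm$sites[keep, ], gm$ref_depth[keep, , drop = FALSE],
                  gm$alt_depth[keep, , drop = FALSE],
                  g[keep, , drop = FALSE])
}

#' Squared dosage correlation between two sites
#'
#' Composite (dosage-correlation) linkage disequilibrium: the squared
#' Pearson correlation of alt-allele dosages over individuals called at
#' both sites. Undefined (`NA`) with fewer than two informative
#' individuals or zero dosage variance at either site.
#'
#' @param site_i,site_j Numeric dosage vectors (0/1/2 with `NA`).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(site_i, site_j) {
  ok <- !is.na(site_i) & !is.na(site_j)
  if (sum(ok) < 2L) return(NA_real_)
  x <- site_i[ok]; y <- site_j[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Distance-binned LD decay
#'
#' Computes r-squared for every intra-chromosomal site pair closer than
#' `max_dist` and averages within half-open distance bins of width
#' `bin_width`. Bins with no defined pair report `n_pairs = 0` and an
#' undefined mean.
#'
#' @param gm A called `genotype_matrix`.
#' @param bin_width Bin width in bp.
#' @param max_dist Maximum pair distance in bp (pairs at or beyond it are
#'   dropped).
#' @param per_chromosome Report bins per chromosome (`TRUE`) or pooled
#'   over chromosomes (`FALSE`); pairs are intra-chromosomal either way.
#' @return A tibble of class `ld_bins` with `distance_lo`, `distance_hi`,
#'   `n_pairs`, `mean_r2` (and `chrom` when per-chromosome).
#' @export
ld_decay <- function(gm, bin_width = 5000, max_dist = 500000,
                     per_chromosome = TRUE) {
  if (is.null(gm$genotype)) gm <- call_genotypes(gm)
  pairs <- ld_pairs(gm, max_dist)
  bin_edges <- seq(0, max_dist, by = bin_width)
  if (tail(bin_edges, 1) < max_dist) bin_edges <- c(bin_edges, max_dist)
  bin_of <- function(d) findInterval(d, bin_edges, rightmost.closed = FALSE)
  template <- tibble(bin = seq_len(length(bin_edges) - 1L),
                     distance_lo = bin_edges[-length(bin_edges)],
                     distance_hi = bin_edges[-1])
  summarise_bins <- function(p) {
    p <- p[!is.na(p$r2), ]
    p$bin <- bin_of(p$distance)
    agg <- p |> group_by(.data$bin) |>
      summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2), .groups = "drop")
    out <- left_join(template, agg, by = "bin")
    out$n_pairs[is.na(out$n_pairs)] <- 0L
    out[, c("distance_lo", "distance_hi", "n_pairs", "mean_r2")]
  }
  out <- if (per_chromosome) {
    bind_rows(lapply(sort(unique(pairs$chrom)), function(ch) {
      mutate(summarise_bins(pairs[pairs$chrom == ch, ]), chrom = ch, .before = 1L)
    }))
  } else {
    summarise_bins(pairs)
  }
  class(out) <- c("ld_bins", class(out))
  out
}

# all intra-chromosomal pairs with distance < max_dist
ld_pairs <- function(gm, max_dist = Inf) {
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    sel <- which(gm$sites$chrom == ch)
    if (length(sel) < 2L) next
    pos <- gm$sites$pos[sel]
    g <- t(gm$genotype[sel, , drop = FALSE])  # individuals x sites
    r2m <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
    nm <- crossprod(!is.na(g))
    r2m[nm < 2L] <- NA_real_
    ut <- which(upper.tri(r2m), arr.ind = TRUE)
    d <- abs(pos[ut[, 2]] - pos[ut[, 1]])
    keep <- d < max_dist
    out[[ch]] <- tibble(chrom = ch,
                        pos_i = pos[ut[keep, 1]], pos_j = pos[ut[keep, 2]],
                        distance = d[keep], r2 = r2m[ut][keep])
  }
  bind_rows(out) %||%
    tibble(chrom = character(), pos_i = numeric(), pos_j = numeric(),
           distance = numeric(), r2 = numeric())
}

#' Per-site observed and expected heterozygosity
#'
#' @param gm A called `genotype_matrix`.
#' @return A tibble with one row per site: `chrom`, `pos`, `n_called`,
#'   `obs_het` (fraction of called individuals heterozygous) and
#'   `exp_het` (`2pq` from the alt-allele frequency).
#' @export
summarize_heterozygosity <- function(gm) {
  if (is.null(gm$genotype)) gm <- call_genotypes(gm)
  g <- gm$genotype
  n_called <- rowSums(!is.na(g))
  obs <- ifelse(n_called > 0, rowSums(g == 1, na.rm = TRUE) / n_called, NA_real_)
  p <- ifelse(n_called > 0, rowSums(g, na.rm = TRUE) / (2 * n_called), NA_real_)
  tibble(chrom = gm$sites$chrom, pos = gm$sites$pos, n_called = n_called,
         obs_het = obs, exp_het = 2 * p * (1 - p))
}
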