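#' Simulate a multi-chromosome genome
#'
#' Chromosome sequences are i.i.d. bases at the requested GC content;
#' deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Lengths in bp (recycled to `n_chrom`).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `sequences` (DNAStringSet named `chr1..chrN`) and
#'   `truth` (tibble `chrom`, `length`).
#' @export
simulate_genome <- function(n_chrom = 3L, chrom_lengths = 2e6, gc = 0.35,
                            seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, n_chrom >= 1)
  lens <- rep_len(chrom_lengths, n_chrom)
  withr::with_seed(seed, {
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  list(sequences = Biostrings::DNAStringSet(seqs),
       truth = tibble(chrom = names(seqs), length = lens))
}

#' Fragment a simulated genome into scaffolds
#'
#' Scaffold lengths follow a lognormal law and tile each chromosome
#' without overlap; about half the scaffolds are reverse-complemented
#' (truth orientation `-`). Optionally, pairs of large scaffolds from
#' different chromosomes are concatenated into chimeric scaffolds with a
#' recorded breakpoint.
#'
#' @param genome Output of [simulate_genome()].
#' @param meanlog,sdlog Lognormal scaffold-length parameters.
#' @param min_length Minimum scaffold length in bp.
#' @param n_chimeric Number of chimeric scaffolds to inject.
#' @param chimera_min_length Minimum piece length for chimera parts.
#' @param seed Integer seed.
#' @return A list with `sequences` (scaffold DNAStringSet) and `truth`
#'   (one row per scaffold piece: `scaffold_id`, `piece`, `chrom`,
#'   `chrom_start`/`chrom_end` 0-based half-open, `orientation`,
#'   `scaf_start`/`scaf_end` on the scaffold, `chimeric`).
#' @export
fragment_genome <- function(genome, meanlog = log(35000), sdlog = 0.7,
                            min_length = 5000, n_chimeric = 0L,
                            chimera_min_length = 40000, seed = 1L) {
  withr::with_seed(seed, {
    pieces <- list()
    for (i in seq_len(nrow(genome$truth))) {
      ch <- genome$truth$chrom[i]
      L <- genome$truth$length[i]
      starts <- 0
      while (tail(starts, 1) < L) {
        len <- max(min_length, round(stats::rlnorm(1, meanlog, sdlog)))
        starts <- c(starts, min(tail(starts, 1) + len, L))
      }
      # avoid a runt final scaffold
      if (length(starts) > 2L &&
          diff(tail(starts, 2)) < min_length) {
        starts <- starts[-(length(starts) - 1L)]
      }
      pieces[[ch]] <- tibble(chrom = ch,
                             chrom_start = starts[-length(starts)],
                             chrom_end = starts[-1])
    }
    pieces <- bind_rows(pieces)
    n <- nrow(pieces)
    pieces$scaffold_id <- sprintf("S%04d", sample.int(n))
    pieces$orientation <- sample(c("+", "-"), n, replace = TRUE)
    pieces$piece <- 1L
    pieces$chimeric <- FALSE
    pieces$scaf_start <- 0
    pieces$scaf_end <- pieces$chrom_end - pieces$chrom_start

    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- substr(as.character(genome$sequences[[pieces$chrom[i]]]),
                  pieces$chrom_start[i] + 1L, pieces$chrom_end[i])
      seqs[i] <- if (pieces$orientation[i] == "-") revcomp(s) else s
    }
    names(seqs) <- pieces$scaffold_id

    if (n_chimeric > 0L) {
      len <- pieces$scaf_end
      cand <- which(len >= chimera_min_length)
      cand <- cand[order(-len[cand])]
      pairs <- list()
      used <- integer()
      for (m in seq_len(n_chimeric)) {
        avail <- setdiff(cand, used)
        pair <- NULL
        for (a in avail) {
          bs <- avail[pieces$chrom[avail] != pieces$chrom[a]]
          if (length(bs) > 0L) { pair <- c(a, bs[1]); break }
        }
        if (is.null(pair)) break
        pairs[[m]] <- pair
        used <- c(used, pair)
      }
      new_pieces <- list()
      for (m in seq_along(pairs)) {
        pair <- pairs[[m]]
        cid <- sprintf("CH%02d", m)
        len_a <- len[pair[1]]
        np <- pieces[pair, ]
        np$scaffold_id <- cid
        np$piece <- c(1L, 2L)
        np$chimeric <- TRUE
        np$scaf_start <- c(0, len_a)
        np$scaf_end <- c(len_a, len_a + len[pair[2]])
        new_pieces[[m]] <- np
        seqs[cid] <- paste0(seqs[pieces$scaffold_id[pair[1]]],
                            seqs[pieces$scaffold_id[pair[2]]])
      }
      if (length(used) > 0L) {
        seqs <- seqs[!names(seqs) %in% pieces$scaffold_id[used]]
        pieces <- bind_rows(pieces[-used, ], bind_rows(new_pieces))
      }
    }
  })
  pieces <- pieces[order(pieces$scaffold_id, pieces$piece), ]
  list(sequences = Biostrings::DNAStringSet(seqs),
       truth = pieces[, c("scaffold_id", "piece", "chrom", "chrom_start",
                          "chrom_end", "orientation", "scaf_start",
                          "scaf_end", "chimeric")])
}

# piecewise-linear monotone cM map per chromosome: segment rates drawn
# lognormally around cm_per_mb
make_cm_maps <- function(genome_truth, cm_per_mb, n_segments = 4L) {
  maps <- list()
  for (i in seq_len(nrow(genome_truth))) {
    L <- genome_truth$length[i]
    bp <- seq(0, L, length.out = n_segments + 1L)
    rates <- cm_per_mb * stats::rlnorm(n_segments, 0, 0.3)
    cm <- c(0, cumsum(rates * diff(bp) / 1e6))
    maps[[genome_truth$chrom[i]]] <- list(bp = bp, cm = cm)
  }
  maps
}

cm_at <- function(map, pos) stats::approx(map$bp, map$cm, xout = pos)$y

#' Simulate two noisy genetic maps plus marker alignments
#'
#' Markers are dropped uniformly over the genome; their true cM position
#' follows a monotone piecewise-linear cM/bp map. Each of the two maps
#' (published/new) observes the true position with independent Gaussian
#' noise. Injected corruptions, realized at exactly the rounded counts:
#' `wrong_lg` markers are assigned a wrong linkage group (in both maps),
#' `discordant_cm` markers get a >30 cM shift in the new map, `multi_map`
#' markers gain a second alignment on another scaffold. A further fraction
#' of markers appears in only one of the two maps.
#'
#' @param scaffolds Output of [fragment_genome()].
#' @param genome Output of [simulate_genome()].
#' @param n_markers Markers per map (before one-map-only thinning).
#' @param cm_per_mb Mean genetic/physical rate. Desk-scale chromosomes are
#'   short in bp, so the default keeps chromosome-realistic cM spans.
#' @param noise_cm_sd Per-map Gaussian cM noise.
#' @param frac_discordant,frac_wrong_lg,frac_multimap Corruption fractions.
#' @param frac_published_only,frac_new_only Fractions present in only one
#'   map.
#' @param marker_length Marker length in bp.
#' @param seed Integer seed.
#' @return A list with `map_published`, `map_new` (genetic-map tibbles),
#'   `psl` (21-column PSL tibble; see [write_psl()]), and `truth` (per
#'   marker: true chrom/pos/cM, scaffold coordinates, corruption label).
#' @export
simulate_maps <- function(scaffolds, genome, n_markers = 400L, cm_per_mb = 40,
                          noise_cm_sd = 0.5, frac_discordant = 0,
                          frac_wrong_lg = 0, frac_multimap = 0,
                          frac_published_only = 0.15, frac_new_only = 0.15,
                          marker_length = 100L, seed = 1L) {
  pieces <- scaffolds$truth
  withr::with_seed(seed, {
    maps <- make_cm_maps(genome$truth, cm_per_mb)
    usable <- pieces[pieces$chrom_end - pieces$chrom_start > 2L * marker_length, ]
    w <- usable$chrom_end - usable$chrom_start
    pick <- sample.int(nrow(usable), n_markers, replace = TRUE, prob = w)
    pos <- floor(usable$chrom_start[pick] +
                   runif(n_markers) * (w[pick] - marker_length))
    chrom <- usable$chrom[pick]
    lg <- sub("^chr", "LG", chrom)
    true_cm <- vapply(seq_len(n_markers),
                      function(i) cm_at(maps[[chrom[i]]], pos[i]), numeric(1))
    marker_id <- sprintf("M%04d", seq_len(n_markers))

    # scaffold-local coordinates, honouring piece orientation
    plen <- usable$chrom_end[pick] - usable$chrom_start[pick]
    off <- pos - usable$chrom_start[pick]
    scaf_pos <- ifelse(usable$orientation[pick] == "+",
                       usable$scaf_start[pick] + off,
                       usable$scaf_start[pick] + plen - off - marker_length)
    scaffold_id <- usable$scaffold_id[pick]

    # disjoint corruption sets, realized exactly
    corruption <- rep("none", n_markers)
    pool <- seq_len(n_markers)
    take <- function(k) {
      k <- min(k, length(pool))
      out <- if (k > 0) sort(sample(pool, k)) else integer()
      pool <<- setdiff(pool, out)
      out
    }
    idx_wrong <- take(round(frac_wrong_lg * n_markers))
    idx_disc <- take(round(frac_discordant * n_markers))
    idx_multi <- take(round(frac_multimap * n_markers))
    corruption[idx_wrong] <- "wrong_lg"
    corruption[idx_disc] <- "discordant_cm"
    corruption[idx_multi] <- "multi_map"
    idx_pub_only <- take(round(frac_published_only * n_markers))
    idx_new_only <- take(round(frac_new_only * n_markers))

    chrom_cm_len <- vapply(maps, function(m) max(m$cm), numeric(1))
    lg_eff <- lg
    cm_base <- true_cm
    for (i in idx_wrong) {
      other <- sample(setdiff(names(maps), chrom[i]), 1)
      lg_eff[i] <- sub("^chr", "LG", other)
      cm_base[i] <- runif(1, 0, chrom_cm_len[[other]])
    }
    cm_pub <- pmax(0, cm_base + rnorm(n_markers, 0, noise_cm_sd))
    cm_new <- pmax(0, cm_base + rnorm(n_markers, 0, noise_cm_sd))
    for (i in idx_disc) {
      delta <- runif(1, 31, 60) + abs(cm_new[i] - cm_pub[i])
      dir <- sample(c(-1, 1), 1)
      if (cm_pub[i] - delta < 0) dir <- 1
      cm_new[i] <- cm_pub[i] + dir * delta
    }

    in_pub <- !seq_len(n_markers) %in% idx_new_only
    in_new <- !seq_len(n_markers) %in% idx_pub_only
    map_published <- tibble(marker_id = marker_id[in_pub],
                            linkage_group = lg_eff[in_pub],
                            cm = cm_pub[in_pub], source = "published")
    map_new <- tibble(marker_id = marker_id[in_new],
                      linkage_group = lg_eff[in_new],
                      cm = cm_new[in_new], source = "new")

    scaf_len <- setNames(Biostrings::width(scaffolds$sequences),
                         names(scaffolds$sequences))
    psl <- psl_row(marker_id, marker_length, scaffold_id,
                   scaf_len[scaffold_id], scaf_pos,
                   usable$orientation[pick])
    extra <- list()
    for (i in idx_multi) {
      other <- sample(setdiff(names(scaf_len)[scaf_len > 3 * marker_length],
                              scaffold_id[i]), 1)
      p2 <- floor(runif(1, 0, scaf_len[[other]] - marker_length))
      extra[[length(extra) + 1L]] <-
        psl_row(marker_id[i], marker_length, other, scaf_len[[other]], p2,
                sample(c("+", "-"), 1))
    }
    psl <- bind_rows(psl, bind_rows(extra))
  })
  truth <- tibble(marker_id = marker_id, chrom = chrom, pos = pos,
                  true_cm = true_cm, linkage_group = lg,
                  scaffold_id = scaffold_id, scaffold_pos = scaf_pos,
                  corruption = corruption,
                  in_published = in_pub, in_new = in_new)
  list(map_published = map_published, map_new = map_new, psl = psl,
       truth = truth)
}

psl_row <- function(qname, qsize, tname, tsize, tstart, strand) {
  tibble(
    matches = qsize, misMatches = 0L, repMatches = 0L, nCount = 0L,
    qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L, tBaseInsert = 0L,
    strand = strand, qName = qname, qSize = qsize, qStart = 0L, qEnd = qsize,
    tName = tname, tSize = as.integer(tsize), tStart = as.integer(tstart),
    tEnd = as.integer(tstart) + qsize, blockCount = 1L,
    blockSizes = paste0(qsize, ","), qStarts = "0,",
    tStarts = paste0(as.integer(tstart), ",")
  )
}

#' Write a 21-column PSL tibble to disk
#'
#' @param psl A PSL tibble, e.g. from [simulate_maps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  readr::write_tsv(psl, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Simulate BAC-end alignments and a physical map
#'
#' BAC clones come in overlapping groups, each group forming one physical
#' contig (the membership truth) with gaps between contigs, plus isolated
#' singleton clones assembled into no contig. Each clone contributes one
#' alignment per end onto the scaffold carrying it (ends spanning a
#' scaffold boundary are dropped). Each sink contig groups `sink_bacs`
#' repeat-derived clones whose end alignments scatter uniformly over
#' scaffolds genome-wide.
#'
#' @param scaffolds Output of [fragment_genome()].
#' @param genome Output of [simulate_genome()].
#' @param n_contigs Number of genuine physical contigs.
#' @param bacs_per_contig Mean clones per contig (at least 2 each).
#' @param n_singletons Isolated clones outside any contig.
#' @param bac_length_mean,bac_length_sd Clone-length law (bp, Gaussian).
#' @param end_length BAC-end read length in bp.
#' @param n_sink_contigs Number of sink contigs to inject.
#' @param sink_bacs Clones per sink contig.
#' @param seed Integer seed.
#' @return A list with `blast6` (12-column tibble; see [write_blast6()]),
#'   `query_lengths`, `memberships` and `truth` (per clone: interval,
#'   contig, sink flag).
#' @export
simulate_bacs <- function(scaffolds, genome, n_contigs = 80L,
                          bacs_per_contig = 5, n_singletons = 60L,
                          bac_length_mean = 20000, bac_length_sd = 3000,
                          end_length = 600L, n_sink_contigs = 1L,
                          sink_bacs = 25L, seed = 1L) {
  pieces <- scaffolds$truth
  withr::with_seed(seed, {
    lens <- genome$truth$length
    rows <- list()
    bid <- 0L
    next_bac <- function() {
      bid <<- bid + 1L
      sprintf("B%04d", bid)
    }
    for (k in seq_len(n_contigs)) {
      cid <- sprintf("ctg%03d", k)
      ci <- sample.int(nrow(genome$truth), 1, prob = lens)
      n_in <- 2L + rpois(1, max(0, bacs_per_contig - 2))
      blen <- pmax(3L * end_length,
                   round(rnorm(n_in, bac_length_mean, bac_length_sd)))
      span <- blen[1] + sum(round(runif(n_in - 1L, 0.2, 0.8) * bac_length_mean))
      s0 <- floor(runif(1) * max(1, lens[ci] - span - max(blen)))
      start <- s0 + c(0, cumsum(round(runif(n_in - 1L, 0.2, 0.8) * bac_length_mean)))
      end <- pmin(start + blen, lens[ci])
      rows[[cid]] <- tibble(
        bac_id = vapply(seq_len(n_in), function(i) next_bac(), character(1)),
        chrom = genome$truth$chrom[ci], start = start, end = end,
        sink = FALSE, contig_id = cid
      )
    }
    ci <- sample.int(nrow(genome$truth), n_singletons, replace = TRUE,
                     prob = lens)
    blen <- pmax(3L * end_length,
                 round(rnorm(n_singletons, bac_length_mean, bac_length_sd)))
    start <- floor(runif(n_singletons) * pmax(1, lens[ci] - blen))
    rows[["singletons"]] <- tibble(
      bac_id = vapply(seq_len(n_singletons), function(i) next_bac(), character(1)),
      chrom = genome$truth$chrom[ci], start = start,
      end = pmin(start + blen, lens[ci]), sink = FALSE,
      contig_id = NA_character_
    )
    bac <- bind_rows(rows)
    n_real <- nrow(bac)

    # map both ends of each genuine clone onto scaffolds
    hit_rows <- list()
    qlens <- list()
    for (i in seq_len(n_real)) {
      for (e in 1:2) {
        estart <- if (e == 1L) bac$start[i] else bac$end[i] - end_length
        eend <- estart + end_length
        pc <- pieces[pieces$chrom == bac$chrom[i] &
                       pieces$chrom_start <= estart &
                       pieces$chrom_end >= eend, ]
        if (nrow(pc) == 0L) next
        pc <- pc[1, ]
        qid <- paste0(bac$bac_id[i], "_", e)
        if (pc$orientation == "+") {
          s0 <- pc$scaf_start + (estart - pc$chrom_start)
          sstart <- s0 + 1; send <- s0 + end_length
        } else {
          s0 <- pc$scaf_start + (pc$chrom_end - eend)
          sstart <- s0 + end_length; send <- s0 + 1
        }
        hit_rows[[qid]] <- tibble(
          query_id = qid, target_id = pc$scaffold_id,
          pident = round(runif(1, 96, 99.5), 2), length = end_length,
          mismatch = 0L, gapopen = 0L, qstart = 1L, qend = end_length,
          sstart = sstart, send = send, evalue = 0, bitscore = 1000
        )
        qlens[[qid]] <- end_length
      }
    }

    # sink contigs: clones with genome-wide scattered end alignments
    scaf_len <- setNames(Biostrings::width(scaffolds$sequences),
                         names(scaffolds$sequences))
    big_enough <- names(scaf_len)[scaf_len > 2L * end_length]
    sink_rows <- list()
    for (k in seq_len(n_sink_contigs)) {
      cid <- sprintf("ctg%03d", 900L + k)
      for (j in seq_len(sink_bacs)) {
        bid <- sprintf("B9%d%02d", k, j)
        sink_rows[[bid]] <- tibble(bac_id = bid, chrom = NA_character_,
                                   start = NA_real_, end = NA_real_,
                                   sink = TRUE, contig_id = cid)
        for (e in 1:2) {
          tgt <- sample(big_enough, 1)
          s0 <- floor(runif(1, 0, scaf_len[[tgt]] - end_length))
          qid <- paste0(bid, "_", e)
          hit_rows[[qid]] <- tibble(
            query_id = qid, target_id = tgt,
            pident = round(runif(1, 96, 99.5), 2), length = end_length,
            mismatch = 0L, gapopen = 0L, qstart = 1L, qend = end_length,
            sstart = s0 + 1, send = s0 + end_length, evalue = 0,
            bitscore = 1000
          )
          qlens[[qid]] <- end_length
        }
      }
    }
    bac <- bind_rows(bac, bind_rows(sink_rows))
  })
  blast6 <- bind_rows(hit_rows)
  memberships <- tibble(bac_id = bac$bac_id, contig_id = bac$contig_id)
  list(
    blast6 = blast6,
    query_lengths = tibble(id = names(qlens),
                           length = as.numeric(unlist(qlens))),
    memberships = memberships,
    truth = bac
  )
}

#' Write a 12-column BLAST tabular tibble to disk
#'
#' @param blast6 A BLAST outfmt-6 tibble, e.g. from [simulate_bacs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(blast6, path) {
  readr::write_tsv(blast6, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Simulate a random-mating population genotyped at GBS-like depth
#'
#' Founder haplotypes carry independent alleles at each site; each
#' generation draws two parents per offspring and recombines each parent's
#' haplotypes with a per-chromosome crossover count that is Poisson in the
#' chromosome's genetic length (Morgans). Read depths are Poisson and
#' allele reads are drawn from the true genotype with a per-read error
#' rate.
#'
#' @param genome Output of [simulate_genome()].
#' @param n_founders Founder individuals (2x haplotypes).
#' @param n_generations Random-mating generations after the founder draw.
#' @param n_individuals Individuals genotyped.
#' @param mean_depth Mean sequencing depth per site and individual.
#' @param error_rate Per-read allele error rate.
#' @param n_sites SNP sites across the genome.
#' @param cm_per_mb Recombination rate used for the Morgan lengths; the
#'   desk-scale default compresses physical, not genetic, scale.
#' @param seed Integer seed.
#' @return A list with `depths` (an uncalled `genotype_matrix`) and
#'   `truth` (list: `genotype` true-dosage matrix, founder `haplotypes`).
#' @export
simulate_population <- function(genome, n_founders = 8L, n_generations = 3L,
                                n_individuals = 60L, mean_depth = 15,
                                error_rate = 0.01, n_sites = 500L,
                                cm_per_mb = 50, seed = 1L) {
  withr::with_seed(seed, {
    lens <- genome$truth$length
    ch_idx <- sort(sample.int(nrow(genome$truth), n_sites, replace = TRUE,
                              prob = lens))
    pos <- floor(runif(n_sites) * lens[ch_idx]) + 1
    ord <- order(ch_idx, pos)
    ch_idx <- ch_idx[ord]; pos <- pos[ord]
    chrom <- genome$truth$chrom[ch_idx]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

    p0 <- runif(n_sites, 0.2, 0.8)
    founders <- matrix(rbinom(2L * n_founders * n_sites, 1L,
                              rep(p0, each = 2L * n_founders)),
                       nrow = 2L * n_founders)

    morgans <- lens / 1e6 * cm_per_mb / 100
    site_chrom_split <- split(seq_len(n_sites), ch_idx)

    gamete <- function(h1, h2) {
      out <- numeric(n_sites)
      for (ci in seq_along(lens)) {
        sel <- site_chrom_split[[as.character(ci)]]
        if (is.null(sel)) next
        k <- rpois(1, morgans[ci])
        cuts <- sort(runif(k, 0, lens[ci]))
        phase <- (findInterval(pos[sel], cuts) + rbinom(1, 1, 0.5)) %% 2
        out[sel] <- ifelse(phase == 0, h1[sel], h2[sel])
      }
      out
    }

    hapA <- founders[sample.int(2L * n_founders, n_individuals, TRUE), , drop = FALSE]
    hapB <- founders[sample.int(2L * n_founders, n_individuals, TRUE), , drop = FALSE]
    for (g in seq_len(n_generations)) {
      newA <- matrix(0, n_individuals, n_sites)
      newB <- matrix(0, n_individuals, n_sites)
      for (i in seq_len(n_individuals)) {
        par <- sample.int(n_individuals, 2L)
        newA[i, ] <- gamete(hapA[par[1], ], hapB[par[1], ])
        newB[i, ] <- gamete(hapA[par[2], ], hapB[par[2], ])
      }
      hapA <- newA; hapB <- newB
    }
    geno <- t(hapA + hapB)  # sites x individuals, alt dosage

    depth <- matrix(rpois(n_sites * n_individuals, mean_depth),
                    nrow = n_sites)
    p_alt <- geno / 2 * (1 - error_rate) + (1 - geno / 2) * error_rate
    altd <- matrix(rbinom(n_sites * n_individuals, as.vector(depth),
                          as.vector(p_alt)), nrow = n_sites)
    refd <- depth - altd
    colnames(refd) <- colnames(altd) <- sprintf("ind%03d", seq_len(n_individuals))
  })
  sites <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  list(depths = genotype_matrix(sites, refd, altd),
       truth = list(genotype = geno, founders = founders))
}
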