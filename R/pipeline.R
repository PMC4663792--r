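#' Default pipeline configuration
#'
#' All thresholds of the anchoring pipeline with their defaults, plus the
#' default desk-scale synthetic scenario. Every constant the pipeline uses
#' is surfaced here; none is hard-coded downstream.
#'
#' @return A named list; see [validate_config()] for the domains.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    min_identity = 0.90,
    min_coverage = 0.90,
    max_discord_cm = 30,
    min_total_unique = 2L,
    min_total_dominant = 4L,
    strong_ratio = 2.0,
    strong_min = 3L,
    gap_length = 10000,
    sink_contig_ids = character(),
    sink_auto = TRUE,
    scenario = list(
      n_chrom = 3L, chrom_length = 2e6, gc = 0.35,
      scaffold_meanlog = log(35000), scaffold_sdlog = 0.7,
      min_scaffold_length = 5000, n_chimeric = 0L,
      n_markers = 400L, cm_per_mb = 40, noise_cm_sd = 0.5,
      frac_discordant = 0, frac_wrong_lg = 0, frac_multimap = 0,
      n_contigs = 80L, bacs_per_contig = 5, n_singletons = 60L,
      n_sink_contigs = 1L
    )
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; every threshold must lie in its documented
#' domain (fractions in `[0, 1]`, positive counts and lengths).
#'
#' @param config A configuration list (see [default_config()]); missing
#'   keys take their defaults.
#' @return The completed configuration, or an error.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$scenario)) {
    unknown <- setdiff(names(config$scenario), names(def$scenario))
    if (length(unknown) > 0L) {
      abort(paste0("unknown scenario key(s): ", paste(unknown, collapse = ", ")))
    }
    def$scenario[names(config$scenario)] <- config$scenario
    config$scenario <- NULL
  }
  def[names(config)] <- config
  cfg <- def
  chk <- function(ok, what) if (!ok) abort(paste0("config: ", what))
  chk(cfg$min_identity >= 0 && cfg$min_identity <= 1, "min_identity must be in [0, 1]")
  chk(cfg$min_coverage >= 0 && cfg$min_coverage <= 1, "min_coverage must be in [0, 1]")
  chk(cfg$max_discord_cm > 0, "max_discord_cm must be positive")
  chk(cfg$min_total_unique >= 1, "min_total_unique must be >= 1")
  chk(cfg$min_total_dominant >= 1, "min_total_dominant must be >= 1")
  chk(cfg$strong_ratio >= 1, "strong_ratio must be >= 1")
  chk(cfg$strong_min >= 1, "strong_min must be >= 1")
  chk(cfg$gap_length >= 1, "gap_length must be >= 1")
  sc <- cfg$scenario
  chk(sc$gc >= 0 && sc$gc <= 1, "scenario gc must be in [0, 1]")
  for (f in c("frac_discordant", "frac_wrong_lg", "frac_multimap")) {
    chk(sc[[f]] >= 0 && sc[[f]] <= 1, paste0("scenario ", f, " must be in [0, 1]"))
  }
  chk(sc$n_chrom >= 1 && sc$n_markers >= 1 && sc$n_contigs >= 0,
      "scenario sizes must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full anchoring pipeline on a synthetic scenario
#'
#' Stage order: simulate inputs (written to `out_dir/inputs` and read back
#' through the package's format readers), filter marker alignments, place
#' markers, resolve linkage groups and split chimeras, classify BAC links,
#' propagate placements, order and orient, build pseudomolecules, and
#' evaluate against the simulation truth. Every stage writes a TSV and
#' reports its counts; a rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param config Configuration list (validated with [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the placements, splits, link calls,
#'   pseudomolecule set, evaluation metrics and the paths written.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pseudomap_run")) {
  cfg <- validate_config(config)
  sc <- cfg$scenario
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  inp <- function(f) file.path(out_dir, "inputs", f)
  outp <- function(f) file.path(out_dir, f)

  inform("stage simulate: generating synthetic scenario")
  genome <- simulate_genome(sc$n_chrom, sc$chrom_length, sc$gc, seed = cfg$seed)
  scaffolds <- fragment_genome(genome, sc$scaffold_meanlog, sc$scaffold_sdlog,
                               sc$min_scaffold_length, sc$n_chimeric,
                               seed = cfg$seed + 1L)
  maps <- simulate_maps(scaffolds, genome, sc$n_markers, sc$cm_per_mb,
                        sc$noise_cm_sd, sc$frac_discordant, sc$frac_wrong_lg,
                        sc$frac_multimap, seed = cfg$seed + 2L)
  bacs <- simulate_bacs(scaffolds, genome, sc$n_contigs, sc$bacs_per_contig,
                        sc$n_singletons, n_sink_contigs = sc$n_sink_contigs,
                        seed = cfg$seed + 3L)
  write_fasta(scaffolds$sequences, inp("scaffolds.fa"))
  write_psl(maps$psl, inp("markers.psl"))
  readr::write_tsv(maps$map_published, inp("map_published.tsv"), progress = FALSE)
  readr::write_tsv(maps$map_new, inp("map_new.tsv"), progress = FALSE)
  write_blast6(bacs$blast6, inp("bac_ends.tsv"))
  readr::write_tsv(bacs$query_lengths, inp("bac_end_lengths.tsv"), progress = FALSE)
  readr::write_tsv(bacs$memberships, inp("physical_map.tsv"), progress = FALSE)

  inform("stage anchor: reading inputs")
  sequences <- read_fasta(inp("scaffolds.fa"))
  hits <- read_psl(inp("markers.psl"))
  map_pub <- read_genetic_map(inp("map_published.tsv"))
  map_new <- read_genetic_map(inp("map_new.tsv"))
  bac_hits <- read_blast6(inp("bac_ends.tsv"),
                          read_query_lengths(inp("bac_end_lengths.tsv")))
  memberships <- read_physical_map(inp("physical_map.tsv"))

  anchored <- anchor_scaffolds(hits, map_pub, map_new, sequences,
                               cfg$min_identity, cfg$min_coverage,
                               cfg$max_discord_cm)
  readr::write_tsv(anchored$markers, outp("markers.tsv"), progress = FALSE)
  readr::write_tsv(anchored$splits, outp("splits.tsv"), progress = FALSE)

  inform("stage bac-links: classifying scaffold-contig links")
  bac_kept <- filter_hits(bac_hits, cfg$min_identity, cfg$min_coverage)
  bac_kept <- filter_sink_contigs(bac_kept, memberships,
                                  cfg$sink_contig_ids, cfg$sink_auto)
  links <- classify_links(bac_kept, cfg$min_total_unique,
                          cfg$min_total_dominant, cfg$strong_ratio,
                          cfg$strong_min)
  readr::write_tsv(links, outp("links.tsv"), progress = FALSE)

  placements <- orient_placements(anchored$placements, anchored$markers)
  # split parents no longer exist as sequences; their halves are handled by
  # the marker stage, so they are not propagation candidates
  links_prop <- links[!links$scaffold_id %in% anchored$splits$scaffold_id, ]
  propagated <- propagate_placement(links_prop, placements)
  all_placements <- bind_rows(
    mutate(placements, anchor_id = NA_character_, sub_rank = NA_integer_),
    propagated
  )
  ordered <- order_scaffolds(all_placements)
  readr::write_tsv(ordered, outp("placements.tsv"), progress = FALSE)

  inform("stage build: constructing pseudomolecules")
  pm <- build_pseudomolecules(ordered, anchored$sequences, cfg$gap_length)
  write_pseudomolecules(pm, outp("genome"), anchored$sequences)

  inform("stage evaluate: scoring against truth")
  ev <- evaluate_anchoring(ordered, scaffolds$truth, anchored$splits)
  readr::write_tsv(ev$metrics, outp("metrics.tsv"), progress = FALSE)

  invisible(list(
    config = cfg, placements = ordered, splits = anchored$splits,
    links = links, markers = anchored$markers, pseudomolecules = pm,
    metrics = ev$metrics, per_chromosome = ev$per_chromosome,
    truth = list(scaffolds = scaffolds$truth, markers = maps$truth,
                 bacs = bacs$truth,
                 sinks_detected = attr(bac_kept, "sink_contigs")),
    out_dir = out_dir
  ))
}
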