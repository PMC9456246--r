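#' Build and validate a run configuration
#'
#' All tunable constants of the FISH and 4C stages live in one validated
#' list; unknown keys are rejected so that a typo cannot silently fall
#' back to a default. Values can be overridden selectively, e.g.
#' `run_config(locus = list(top_k = 100))`.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   key-wise).
#' @return A validated `run_config` list with components `spacing`
#'   (`dz`, `dy`, `dx` nm), `nucleus` (`min_vox`, `max_vox`, `stop_frac`,
#'   `init_radius`, `beta`), `locus` and `territory` (`top_k`, `min_vox`,
#'   `max_vox`), `connectivity`, `cutoff_nm`, `quantile`, `fourc`
#'   (`site`, `cut_offset`, `end_tolerance`, `window`, `scale`,
#'   `min_len`, `mask_bait`), `seed`.
#' @export
run_config <- function(...) {
  defaults <- list(
    spacing = c(dz = 400, dy = 200, dx = 200),
    nucleus = list(min_vox = 1000, max_vox = 1e6, stop_frac = 0.3,
                   init_radius = 10, beta = 0.5),
    locus = list(top_k = 300, min_vox = 10, max_vox = 500),
    territory = list(top_k = 3000, min_vox = 100, max_vox = 50000),
    connectivity = 26,
    cutoff_nm = 2000,
    quantile = 0.99,
    fourc = list(site = "AAGCTT", cut_offset = 1, end_tolerance = 4,
                 window = 5e5, scale = 1e6, min_len = 20, mask_bait = TRUE),
    seed = 1
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == ""))
    stop("configuration overrides must be named")
  for (nm in nms) {
    full <- paste0(path, nm)
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration key: '%s'", full))
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]], paste0(full, "$"))
    else
      base[[nm]] <- overrides[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  sp <- as_spacing(cfg$spacing)
  if (any(sp <= 0)) stop("config: spacing must be strictly positive")
  with(cfg$nucleus, stopifnot(min_vox <= max_vox, stop_frac > 0, stop_frac < 1,
                              init_radius > 0, beta > 0, beta < 1))
  with(cfg$locus, stopifnot(min_vox <= max_vox, top_k >= 0))
  with(cfg$territory, stopifnot(min_vox <= max_vox, top_k >= 0))
  if (!cfg$connectivity %in% c(6, 18, 26)) stop("config: connectivity must be 6, 18 or 26")
  stopifnot(cfg$cutoff_nm > 0, cfg$quantile > 0, cfg$quantile < 1)
  with(cfg$fourc, stopifnot(nchar(site) >= 1, cut_offset >= 0,
                            end_tolerance >= 0, window > 0, scale > 0,
                            min_len >= 1))
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full FISH quantification pipeline
#'
#' Executes despeckle -> nucleus detection -> locus/territory detection
#' -> size filtering -> mutual-nearest-neighbour pairing -> cell QC ->
#' distance measurement on each field, then break-calling statistics:
#' the break threshold is the configured quantile (99th by default) of
#' the control pair-distance distribution, the treated cohort is
#' classified against it, and the empirical tail test is applied to the
#' treated broken fraction. Also emits a binned distance histogram table
#' and a scatter table of pair distance versus signed territory distance
#' per locus.
#'
#' @param fields a list of fields; each field is a named list of
#'   [voxel_stack()]s (`dapi`, `probe1`, `probe2`, `paint`) or a named
#'   character vector of TIFF paths with those names.
#' @param config a [run_config()].
#' @param control_distances optional pair distances (nm) from a control
#'   run; when supplied, the break threshold is derived from them and
#'   this run is treated as the treated cohort. When absent, this run's
#'   own distances define the threshold (control mode).
#' @param out_dir optional directory for CSV/JSON outputs and the run
#'   manifest.
#' @return List with `cells` (per-cell QC table), `pairs` (per-pair
#'   distances from QC-passing cells), `stats` (threshold, break calls,
#'   tail test), `histogram` (100-nm binned pair-distance counts) and
#'   `scatter` (pair distance vs signed territory distance per locus).
#' @export
run_fish_pipeline <- function(fields, config = run_config(),
                              control_distances = NULL, out_dir = NULL) {
  stopifnot(length(fields) >= 1)
  sp <- as_spacing(config$spacing)
  cells <- NULL
  pairs_all <- NULL
  for (fi in seq_along(fields)) {
    field <- load_field(fields[[fi]], sp)
    field <- lapply(field, despeckle)
    nuclei <- detect_nuclei(field$dapi,
                            min_vox = config$nucleus$min_vox,
                            max_vox = config$nucleus$max_vox,
                            stop_frac = config$nucleus$stop_frac,
                            init_radius = config$nucleus$init_radius,
                            beta = config$nucleus$beta)
    for (nuc in nuclei) {
      cell_id <- sprintf("f%d_n%d", fi, nuc$nucleus_id)
      rec <- measure_cell(field, nuc, config, sp, cell_id)
      rec_row <- data.frame(cell_id = cell_id,
                            n_probe1 = rec$n_probe1, n_probe2 = rec$n_probe2,
                            n_territories = rec$n_territories,
                            qc_pass = rec$qc_pass, qc_reason = rec$qc_reason)
      cells <- rbind(cells, rec_row)
      if (rec$qc_pass && nrow(rec$pairs) > 0) {
        rec$pairs$cell_id <- cell_id
        pairs_all <- rbind(pairs_all, rec$pairs)
      }
    }
  }
  if (is.null(cells)) cells <- data.frame()
  if (is.null(pairs_all))
    pairs_all <- data.frame(pair_distance_nm = numeric(0),
                            territory_dist1_nm = numeric(0),
                            territory_dist2_nm = numeric(0))

  distances <- pairs_all$pair_distance_nm
  stats <- list()
  if (length(distances) >= 10) {
    ctl <- if (is.null(control_distances)) distances else control_distances
    thr <- broken_threshold(ctl, q = config$quantile)
    calls <- classify_broken(distances, thr)
    stats <- list(threshold_nm = thr,
                  broken_fraction = calls$broken_fraction,
                  n_pairs = length(distances),
                  tail = tail_test(calls$broken_fraction, length(distances)),
                  calls = calls)
  }
  histogram <- if (length(distances)) {
    bin <- floor(distances / 100)
    nb <- max(bin) + 1L
    data.frame(bin_lo_nm = 100 * (seq_len(nb) - 1L),
               bin_hi_nm = 100 * seq_len(nb),
               count = tabulate(bin + 1L, nb))
  } else data.frame()
  scatter <- if (nrow(pairs_all)) {
    data.frame(cell_id = rep(pairs_all$cell_id, 2),
               pair_distance_nm = rep(pairs_all$pair_distance_nm, 2),
               locus = rep(1:2, each = nrow(pairs_all)),
               territory_dist_nm = c(pairs_all$territory_dist1_nm,
                                     pairs_all$territory_dist2_nm))
  } else data.frame()

  out <- list(cells = cells, pairs = pairs_all, stats = stats,
              histogram = histogram, scatter = scatter)
  if (!is.null(out_dir)) write_fish_outputs(out, config, out_dir)
  out
}

load_field <- function(field, sp) {
  need <- c("dapi", "probe1", "probe2", "paint")
  if (is.character(field)) {
    stopifnot(all(need %in% names(field)))
    field <- sapply(need, function(nm) read_stack_tiff(field[nm], sp, nm),
                    simplify = FALSE)
  }
  stopifnot(all(need %in% names(field)),
            all(vapply(field[need], inherits, logical(1), "voxel_stack")))
  field[need]
}

measure_cell <- function(field, nuc, config, sp, cell_id) {
  p1 <- size_filter(detect_objects(field$probe1, nuc, "locus",
                                   top_k = config$locus$top_k,
                                   connectivity = config$connectivity),
                    config$locus$min_vox, config$locus$max_vox)
  p2 <- size_filter(detect_objects(field$probe2, nuc, "locus",
                                   top_k = config$locus$top_k,
                                   connectivity = config$connectivity),
                    config$locus$min_vox, config$locus$max_vox)
  terr <- size_filter(detect_objects(field$paint, nuc, "territory",
                                     top_k = config$territory$top_k,
                                     connectivity = config$connectivity),
                      config$territory$min_vox, config$territory$max_vox)
  g <- lapply(p1, weighted_centroid, spacing = sp)
  r <- lapply(p2, weighted_centroid, spacing = sp)
  pairing <- pair_loci(g, r)
  pairs <- pairing$pairs
  if (nrow(pairs) > 0) {
    td <- function(pt) {
      if (length(terr) == 0) return(NA_real_)
      ds <- vapply(terr, function(tt)
        signed_territory_distance(pt, tt, sp, config$connectivity), numeric(1))
      ds[which.min(abs(ds))]      # nearest territory
    }
    pairs$pair_distance_nm <- pairs$distance_nm
    pairs$territory_dist1_nm <- vapply(pairs$green, function(i) td(g[[i]]), numeric(1))
    pairs$territory_dist2_nm <- vapply(pairs$red, function(i) td(r[[i]]), numeric(1))
  } else {
    pairs$pair_distance_nm <- numeric(0)
    pairs$territory_dist1_nm <- numeric(0)
    pairs$territory_dist2_nm <- numeric(0)
  }
  cell <- list(cell_id = cell_id, n_probe1 = length(p1), n_probe2 = length(p2),
               n_territories = length(terr), pairs = pairs,
               loci1 = g, loci2 = r)
  qc_cell(cell, cutoff_nm = config$cutoff_nm)
}

write_fish_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(out$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(out$histogram, file.path(out_dir, "histogram.csv"), row.names = FALSE)
  utils::write.csv(out$scatter, file.path(out_dir, "scatter.csv"), row.names = FALSE)
  st <- out$stats
  st$calls <- NULL
  if (!is.null(st$tail)) st$tail <- unclass(st$tail)
  jsonlite::write_json(st, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(config, out_dir)
  invisible(out_dir)
}

write_manifest <- function(config, out_dir) {
  manifest <- list(package = "breakfish",
                   version = as.character(utils::packageVersion("breakfish")),
                   r_version = R.version.string,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Run the full 4C-seq pipeline
#'
#' digest -> demultiplex -> exact mapping -> fragment-end counting ->
#' bait masking -> replicate normalisation and merging -> windowed
#' profile -> trans fraction -> (optional) partner-gene enrichment, for
#' each anchor.
#'
#' @param genome FASTA path, named character vector or `DNAStringSet`.
#' @param fastq named list/vector: per-replicate FASTQ paths, or
#'   in-memory named read vectors.
#' @param anchors data.frame (`anchor_id`, `primer`, `bait_chrom`,
#'   `bait_fragment_index`) or path to the YAML written by
#'   [write_fourc_dataset()].
#' @param config a [run_config()] (the `fourc` block is used).
#' @param genes,partners optional gene table (BED path or data.frame) and
#'   partner subset for [partner_enrichment()].
#' @param out_dir optional output directory (fragment BED, per-anchor
#'   signal TSV and bedGraph, stats JSON, manifest).
#' @return List with `fragments`, per-anchor results (`signals` merged
#'   signal, `r_min` replicate correlation, `profile`, `trans_fraction`,
#'   `enrichment` or `NULL`) under `anchors`, and the per-replicate
#'   read-accounting table `read_counts`.
#' @export
run_fourc_pipeline <- function(genome, fastq, anchors, config = run_config(),
                               genes = NULL, partners = NULL, out_dir = NULL) {
  fc <- config$fourc
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  genome <- as_genome(genome)
  if (is.character(anchors) && length(anchors) == 1L && file.exists(anchors))
    anchors <- do.call(rbind, lapply(yaml::read_yaml(anchors), as.data.frame))
  validate_anchors(anchors)
  if (is.character(genes) && length(genes) == 1L) genes <- read_bed(genes)

  fragments <- digest_genome(genome, site = fc$site, cut_offset = fc$cut_offset)
  reps <- lapply(fastq, function(f) {
    if (length(f) == 1L && file.exists(f))
      Biostrings::readDNAStringSet(f, format = "fastq")
    else f
  })
  read_counts <- NULL
  per_anchor <- vector("list", nrow(anchors))
  names(per_anchor) <- anchors$anchor_id
  parsed <- lapply(seq_along(reps), function(ri) {
    pr <- parse_reads(reps[[ri]], anchors, site = fc$site)
    read_counts <<- rbind(read_counts,
                          data.frame(replicate = names(reps)[ri] %||% ri,
                                     t(attr(pr, "counts"))))
    pr
  })
  for (ai in seq_len(nrow(anchors))) {
    sig_reps <- lapply(parsed, function(pr) {
      sel <- pr$category == "classified" & pr$anchor_id == anchors$anchor_id[ai]
      mapped <- map_exact(pr$captured[sel], genome, min_len = fc$min_len)
      sg <- fragment_signal(mapped, fragments, end_tolerance = fc$end_tolerance)
      if (isTRUE(fc$mask_bait))
        sg <- mask_bait_fragments(sg, anchors$bait_chrom[ai],
                                  anchors$bait_fragment_index[ai])
      sg
    })
    empty <- vapply(sig_reps, function(s) sum(s$raw) == 0, logical(1))
    if (all(empty)) {
      warning(sprintf("anchor %s: no classified reads produced signal",
                      anchors$anchor_id[ai]))
      per_anchor[[ai]] <- list(signals = NULL, r_min = NA_real_,
                               profile = NULL, trans_fraction = NA_real_,
                               enrichment = NULL)
      next
    }
    if (length(sig_reps) >= 2) {
      nm <- normalize_and_merge(sig_reps, scale = fc$scale, window = fc$window)
      merged <- nm$merged
      r_min <- nm$r_min
    } else {
      merged <- sig_reps[[1]]
      merged$normalized <- merged$raw * fc$scale / sum(merged$raw)
      r_min <- NA_real_
    }
    profile <- window_profile(merged, window = fc$window)
    tf <- trans_fraction(merged, anchors$bait_chrom[ai])
    enr <- if (!is.null(genes) && !is.null(partners)) {
      partner_enrichment(merged, genes, partners, anchors$bait_chrom[ai],
                         window = fc$window)
    } else NULL
    per_anchor[[ai]] <- list(signals = merged, r_min = r_min, profile = profile,
                             trans_fraction = tf, enrichment = enr)
  }
  out <- list(fragments = fragments, anchors = per_anchor,
              read_counts = read_counts)
  if (!is.null(out_dir)) write_fourc_outputs(out, anchors, config, out_dir)
  out
}

write_fourc_outputs <- function(out, anchors, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out$fragments[, c("chrom", "start", "end", "frag_id")],
                     file.path(out_dir, "fragments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  stats <- list()
  for (aid in names(out$anchors)) {
    res <- out$anchors[[aid]]
    if (is.null(res$signals)) next
    utils::write.table(res$signals,
                       file.path(out_dir, sprintf("signal_%s.tsv", aid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(res$profile,
                   file.path(out_dir, sprintf("profile_%s.bedGraph", aid)),
                   track_name = aid)
    stats[[aid]] <- list(r_min = res$r_min,
                         trans_fraction = res$trans_fraction,
                         enrichment = if (!is.null(res$enrichment))
                           res$enrichment[c("U", "p_value")] else NULL)
  }
  if (!is.null(out$read_counts))
    utils::write.csv(out$read_counts, file.path(out_dir, "read_counts.csv"),
                     row.names = FALSE)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(config, out_dir)
  invisible(out_dir)
}
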