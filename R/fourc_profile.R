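#' Windowed contact profile
#'
#' Partitions each chromosome into non-overlapping half-open windows
#' starting at 0 (500 kb by default), assigns each restriction fragment
#' to the window containing its midpoint, and reports per window the
#' number of assigned fragments carrying at least one 4C-captured
#' contact (`raw >= 1`). Counting signal-bearing fragments rather than
#' reads flattens PCR amplification artefacts.
#'
#' @param signals a `fragment_signal` from [fragment_signal()].
#' @param window window size in bp (default 5e5).
#' @return A `window_profile`: data.frame with `chrom`, `start`, `end`
#'   (0-based half-open; the last window is clipped to the chromosome
#'   length) and `value`.
#' @export
window_profile <- function(signals, window = 5e5) {
  stopifnot(window > 0)
  lens <- attr(signals, "chrom_lengths")
  if (is.null(lens)) stop("window_profile: signals carry no chromosome lengths")
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    ci <- names(lens)[i]
    L <- lens[[i]]
    nwin <- max(1L, ceiling(L / window))
    starts <- (seq_len(nwin) - 1L) * window
    rows <- signals$chrom == ci & signals$raw >= 1L
    mids <- (signals$start[rows] + signals$end[rows]) %/% 2
    w <- pmin(mids %/% window + 1L, nwin)
    out[[i]] <- data.frame(chrom = ci, start = starts,
                           end = pmin(starts + window, L),
                           value = tabulate(w, nwin))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_profile", "data.frame")
  res
}

#' Normalise replicates to a common library size and merge
#'
#' Each replicate is scaled so its total assigned read count equals
#' `scale` (`normalized = raw * scale / sum(raw)`, signal per million by
#' default), then the replicates are merged by averaging the normalised
#' values. The Pearson correlation of the replicates' windowed contact
#' profiles is reported as the replicate-agreement statistic.
#'
#' @param replicates list of `fragment_signal`s sharing one fragment map.
#' @param scale normalisation target in reads (default 1e6).
#' @param window window size used for the correlation profile.
#' @return List with `merged` (a `fragment_signal` carrying `raw` =
#'   summed raw counts and `normalized` = mean normalised signal),
#'   `r` (pairwise Pearson correlation matrix of window profiles) and
#'   `r_min` (its smallest off-diagonal entry; equals the single r for
#'   two replicates).
#' @export
normalize_and_merge <- function(replicates, scale = 1e6, window = 5e5) {
  stopifnot(is.list(replicates), length(replicates) >= 2)
  ids <- replicates[[1]]$frag_id
  for (r in replicates[-1])
    if (!identical(r$frag_id, ids))
      stop("normalize_and_merge: replicates must share one fragment map")
  sums <- vapply(replicates, function(r) sum(r$raw), numeric(1))
  if (any(sums == 0)) stop("normalize_and_merge: a replicate has zero assigned reads")
  norm <- vapply(seq_along(replicates),
                 function(i) replicates[[i]]$raw * scale / sums[i],
                 numeric(length(ids)))
  merged <- replicates[[1]]
  merged$raw <- as.integer(Reduce(`+`, lapply(replicates, `[[`, "raw")))
  merged$normalized <- rowMeans(norm)
  profs <- matrix(unlist(lapply(replicates,
                                function(r) window_profile(r, window)$value)),
                  ncol = length(replicates))
  if (nrow(profs) < 2) {
    warning("normalize_and_merge: fewer than 2 windows; replicate correlation undefined")
    rmat <- matrix(NA_real_, length(replicates), length(replicates))
  } else {
    rmat <- suppressWarnings(stats::cor(profs))
  }
  offdiag <- rmat[lower.tri(rmat)]
  list(merged = merged, r = rmat, r_min = min(offdiag))
}

#' Fraction of trans contacts
#'
#' The proportion of signal-bearing restriction fragments (`raw >= 1`)
#' lying on chromosomes other than the bait chromosome — the
#' fragment-level analogue of the windowed contact definition.
#'
#' @param signals a `fragment_signal`.
#' @param bait_chrom bait chromosome name.
#' @return Proportion in `[0, 1]`; an error if no fragment carries
#'   signal.
#' @export
trans_fraction <- function(signals, bait_chrom) {
  sb <- signals$raw >= 1L
  if (!any(sb)) stop("trans_fraction: no signal-bearing fragments")
  mean(signals$chrom[sb] != bait_chrom)
}

#' Partner-gene enrichment of 4C signal
#'
#' Compares the 4C signal over a set of candidate partner genes with the
#' signal over all other genes on non-bait chromosomes using the
#' Mann-Whitney test. Per-gene signal is, at window level (default), the
#' sum of windowed contact counts over the windows overlapping the gene;
#' at fragment level, the number of signal-bearing fragments overlapping
#' the gene.
#'
#' @param signals a `fragment_signal`.
#' @param genes data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `name` — e.g. read from a BED file.
#' @param partners character vector of partner gene names; must be a
#'   nonempty subset of `genes$name` on non-bait chromosomes.
#' @param bait_chrom bait chromosome (its genes are excluded from both
#'   groups).
#' @param level `"window"` (default) or `"fragment"`.
#' @param window window size for window-level signal.
#' @param alternative passed to [mann_whitney()].
#' @return List with `U`, `p_value`, `exact` and `table` (per-gene
#'   signal with an `is_partner` flag).
#' @export
partner_enrichment <- function(signals, genes, partners, bait_chrom,
                               level = c("window", "fragment"),
                               window = 5e5,
                               alternative = c("two.sided", "greater")) {
  level <- match.arg(level)
  alternative <- match.arg(alternative)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (length(partners) == 0L) stop("partner_enrichment: empty partner set")
  if (!all(partners %in% genes$name))
    stop("partner_enrichment: partners must be a subset of the gene list")
  genes <- genes[genes$chrom != bait_chrom, , drop = FALSE]
  if (!all(partners %in% genes$name))
    stop("partner_enrichment: partners must lie on non-bait chromosomes")
  if (!any(!(genes$name %in% partners)))
    stop("partner_enrichment: no background genes left on non-bait chromosomes")

  if (level == "window") {
    prof <- window_profile(signals, window)
    src <- GenomicRanges::GRanges(prof$chrom,
                                  IRanges::IRanges(prof$start + 1L, prof$end))
    val <- prof$value
  } else {
    sb <- signals$raw >= 1L
    src <- GenomicRanges::GRanges(signals$chrom[sb],
                                  IRanges::IRanges(signals$start[sb] + 1L,
                                                   signals$end[sb]))
    val <- rep(1L, sum(sb))
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  # profiles legitimately cover chromosomes (e.g. the bait's) absent
  # from the gene list
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, src))
  signal <- vapply(seq_along(gr), function(i)
    sum(val[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]),
    numeric(1))
  is_partner <- genes$name %in% partners
  mw <- mann_whitney(signal[is_partner], signal[!is_partner], alternative)
  list(U = mw$U, p_value = mw$p_value, exact = mw$exact,
       table = data.frame(name = genes$name, chrom = genes$chrom,
                          signal = signal, is_partner = is_partner))
}

#' Read a BED file of gene intervals
#'
#' Minimal BED (chrom, start, end, name) reader; coordinates stay
#' 0-based half-open as in the format.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name")[1:4])
  df
}

#' Write a window profile as bedGraph
#'
#' @param profile a `window_profile`.
#' @param path output path.
#' @param track_name bedGraph track name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, track_name = "fourc") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", profile$chrom,
                     as.integer(profile$start), as.integer(profile$end),
                     profile$value), con)
  invisible(path)
}
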