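#' Simulate a 4C-seq dataset with known ground truth
#'
#' Builds a toy multi-chromosome genome of random sequence (HindIII
#' sites occur naturally, about one per 4 kb), plants one bait primer per
#' anchor immediately upstream of a HindIII site on the bait chromosome,
#' and emits reads of the form `primer + AAGCTT + fragment-end prefix`.
#' Target fragments are drawn from a distance-decay contact model: on the
#' bait chromosome the probability of fragment `i` is proportional to
#' `(1 + |i - bait|)^(-alpha)` (fragment-index distance), and every
#' eligible trans fragment receives the uniform weight `trans_floor`.
#' Captures start at the left fragment end (plus strand) or the right end
#' (minus strand, reverse-complemented) with equal probability. Only
#' fragments long enough to donate a capture and whose end seeds are
#' unique genome-wide are eligible, so every planted read is uniquely
#' mappable and the per-fragment planted counts are recoverable exactly.
#' The bait fragment and its two neighbours never receive planted
#' contacts (in a real library those positions hold self-ligation
#' products, which the counting path masks). A configurable fraction of
#' junk reads (no ligation site, or an unknown primer) is appended and
#' the whole read set shuffled.
#'
#' @param n_chrom,chrom_len chromosome count and length (bp).
#' @param n_anchors anchors to plant (all on chromosome 1, the bait
#'   chromosome).
#' @param alpha cis distance-decay exponent (default 1).
#' @param trans_floor uniform per-fragment trans weight (default 0.002;
#'   0 disables trans contacts entirely).
#' @param n_reads reads per anchor per replicate (junk included).
#' @param junk_fraction fraction of junk reads; `round(junk_fraction *
#'   n_reads)` junk reads are emitted, the rest carry a valid
#'   anchor+site structure.
#' @param n_replicates independent replicates (default 2).
#' @param cap_len captured-sequence length in bp (default 30).
#' @param primer_len planted primer length (default 22).
#' @param site primary-enzyme motif (HindIII `AAGCTT`).
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output.
#' @param out_dir if given, write `genome.fa`, per-replicate FASTQ files,
#'   the fragment map as BED and the planted counts as TSV.
#' @return A `fourc_truth`: list with `genome` (`DNAStringSet`),
#'   `fragments` (a `fragment_map`), `anchors` (data.frame `anchor_id`,
#'   `primer`, `bait_chrom`, `bait_fragment_index`), `planted_counts`
#'   (data.frame `anchor_id`, `replicate`, `frag_id`, `count`), `reads`
#'   (list per replicate of named read-sequence vectors), `n_junk` (per
#'   replicate), `contact_prob` (data.frame `frag_id`, `prob` of the
#'   sampling model) and `files` (paths when `out_dir` was given).
#' @export
simulate_fourc_dataset <- function(n_chrom = 3, chrom_len = 1e6,
                                   n_anchors = 1,
                                   alpha = 1, trans_floor = 0.002,
                                   n_reads = 10000, junk_fraction = 0.1,
                                   n_replicates = 2,
                                   cap_len = 30, primer_len = 22,
                                   site = "AAGCTT", seed = 1,
                                   out_dir = NULL) {
  stopifnot(n_chrom >= 1, chrom_len >= 10000, junk_fraction >= 0, junk_fraction < 1,
            trans_floor >= 0, n_replicates >= 1, n_anchors >= 1)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(bases, chrom_len, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  bait_chrom <- "chr1"

  # plant one primer per anchor directly upstream of a natural HindIII site
  sites <- gregexpr(site, seqs[bait_chrom], fixed = TRUE)[[1]]
  if (length(sites) == 1L && sites[1] == -1L)
    stop("no HindIII sites on the bait chromosome")
  sites <- sites[sites > primer_len + 100 & sites < chrom_len - 10 * cap_len]
  if (length(sites) < n_anchors) stop("not enough HindIII sites to plant anchors")
  plant_at <- sort(sample(sites, n_anchors))
  primers <- character(n_anchors)
  for (a in seq_len(n_anchors)) {
    repeat {
      pr <- paste(sample(bases, primer_len, replace = TRUE), collapse = "")
      # the primer must not contain the site, must end cleanly before it,
      # and must not occur anywhere else in the genome
      if (grepl(site, paste0(pr, site), fixed = TRUE) &&
          regexpr(site, paste0(pr, site), fixed = TRUE) == primer_len + 1 &&
          !any(vapply(seqs, function(s) grepl(pr, s, fixed = TRUE), logical(1))) &&
          !pr %in% primers) {
        primers[a] <- pr
        break
      }
    }
    s0 <- plant_at[a]              # 1-based site start
    substr(seqs[bait_chrom], s0 - primer_len, s0 - 1L) <- primers[a]
  }
  # planting must not have duplicated a primer or destroyed its site
  for (a in seq_len(n_anchors)) {
    occ <- sum(vapply(seqs, function(s)
      length(gregexpr(primers[a], s, fixed = TRUE)[[1]]) *
        (gregexpr(primers[a], s, fixed = TRUE)[[1]][1] != -1L), numeric(1)))
    if (occ != 1) stop("primer planting collision; choose a different seed")
  }

  genome <- Biostrings::DNAStringSet(seqs)
  fragments <- digest_genome(genome, site = site, cut_offset = 1)
  bait_index <- vapply(plant_at, function(s0) {
    i <- which(fragments$chrom == bait_chrom & fragments$start == s0)  # cut at s0-1+1 = s0 (0-based)
    if (length(i) != 1L) stop("bait fragment not found after digestion")
    fragments$index[i]
  }, integer(1))
  anchors <- data.frame(anchor_id = sprintf("anchor%d", seq_len(n_anchors)),
                        primer = primers,
                        bait_chrom = bait_chrom,
                        bait_fragment_index = bait_index)

  eligible <- eligible_fragments(fragments, genome, cap_len, bait_chrom, bait_index)
  n_junk <- round(junk_fraction * n_reads)
  n_signal <- n_reads - n_junk

  planted <- NULL
  reads <- vector("list", n_replicates)
  contact_prob <- NULL
  for (rep_i in seq_len(n_replicates)) {
    rep_seqs <- character(0)
    for (a in seq_len(n_anchors)) {
      w <- contact_weights(fragments, eligible, bait_chrom, bait_index[a],
                           alpha, trans_floor)
      if (rep_i == 1L && a == 1L)
        contact_prob <- data.frame(frag_id = fragments$frag_id, prob = w / sum(w))
      pick <- sample.int(nrow(fragments), n_signal, replace = TRUE, prob = w)
      ends <- sample(c("L", "R"), n_signal, replace = TRUE)
      caps <- extract_captures(fragments, seqs, pick, ends, cap_len)
      rep_seqs <- c(rep_seqs, paste0(primers[a], site, caps))
      tab <- table(fragments$frag_id[pick])
      planted <- rbind(planted,
                       data.frame(anchor_id = anchors$anchor_id[a],
                                  replicate = rep_i,
                                  frag_id = names(tab),
                                  count = as.integer(tab)))
      # junk for this anchor's share
      if (n_junk > 0)
        rep_seqs <- c(rep_seqs, make_junk_reads(n_junk, nchar(rep_seqs[1]),
                                                site, primers))
    }
    rep_seqs <- rep_seqs[sample.int(length(rep_seqs))]
    names(rep_seqs) <- sprintf("rep%d_read_%06d", rep_i, seq_along(rep_seqs))
    reads[[rep_i]] <- rep_seqs
  }
  names(reads) <- sprintf("rep%d", seq_len(n_replicates))
  rownames(planted) <- NULL

  out <- structure(list(genome = genome, fragments = fragments,
                        anchors = anchors, planted_counts = planted,
                        reads = reads,
                        n_junk = rep(n_junk * n_anchors, n_replicates),
                        contact_prob = contact_prob,
                        params = list(seed = seed, alpha = alpha,
                                      trans_floor = trans_floor,
                                      n_reads = n_reads,
                                      junk_fraction = junk_fraction,
                                      cap_len = cap_len, site = site)),
                   class = "fourc_truth")
  if (!is.null(out_dir)) out$files <- write_fourc_dataset(out, out_dir)
  out
}

# fragments long enough to donate a capture, with both end seeds unique
# genome-wide, excluding the bait fragment and its immediate neighbours
eligible_fragments <- function(fragments, genome, cap_len, bait_chrom, bait_index,
                               seed_len = 20) {
  ok <- (fragments$end - fragments$start) >= (2 * cap_len)
  for (bi in bait_index)
    ok <- ok & !(fragments$chrom == bait_chrom & abs(fragments$index - bi) <= 1)
  idx <- which(ok)
  left <- as.character(Biostrings::subseq(genome[fragments$chrom[idx]],
                                          fragments$start[idx] + 1L,
                                          fragments$start[idx] + seed_len))
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[fragments$chrom[idx]],
                       fragments$end[idx] - seed_len + 1L,
                       fragments$end[idx])))
  uq <- unique(c(left, right))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq))
  counts <- integer(length(uq))
  for (ci in seq_along(genome)) {
    counts <- counts + S4Vectors::elementNROWS(Biostrings::matchPDict(pd, genome[[ci]])) +
      S4Vectors::elementNROWS(Biostrings::matchPDict(pd, Biostrings::reverseComplement(genome[[ci]])))
  }
  unique_seed <- counts == 1L
  good <- unique_seed[match(left, uq)] & unique_seed[match(right, uq)]
  keep <- logical(nrow(fragments))
  keep[idx[good]] <- TRUE
  keep
}

contact_weights <- function(fragments, eligible, bait_chrom, bait_index,
                            alpha, trans_floor) {
  w <- numeric(nrow(fragments))
  cis <- fragments$chrom == bait_chrom
  w[cis] <- (1 + abs(fragments$index[cis] - bait_index))^(-alpha)
  w[!cis] <- trans_floor
  w[!eligible] <- 0
  if (sum(w) <= 0) stop("contact model leaves no eligible target fragments")
  w
}

extract_captures <- function(fragments, seqs, pick, ends, cap_len) {
  chrom <- fragments$chrom[pick]
  s <- unname(seqs[chrom])
  caps <- character(length(pick))
  left <- ends == "L"
  caps[left] <- substr(s[left], fragments$start[pick[left]] + 1L,
                       fragments$start[pick[left]] + cap_len)
  if (any(!left)) {
    tails <- substr(s[!left], fragments$end[pick[!left]] - cap_len + 1L,
                    fragments$end[pick[!left]])
    caps[!left] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tails)))
  }
  caps
}

make_junk_reads <- function(n, read_len, site, primers) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    m <- matrix(sample(bases, k * read_len, replace = TRUE), nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  out <- draw(n)
  repeat {
    # a junk read must never look like a valid anchor + site read
    pos <- regexpr(site, out, fixed = TRUE)
    pre <- substr(out, 1, pmax(pos - 1, 0))
    bad <- pos >= 2 &
      Reduce(`|`, lapply(primers, function(p) startsWith(pre, p)))
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

#' Write a simulated 4C dataset to disk
#'
#' @param truth a `fourc_truth` from [simulate_fourc_dataset()].
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_fourc_dataset <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(truth$genome, paths["genome"])
  for (rn in names(truth$reads)) {
    p <- file.path(dir, sprintf("reads_%s.fastq", rn))
    write_fastq(truth$reads[[rn]], p)
    paths[paste0("reads_", rn)] <- p
  }
  fb <- file.path(dir, "fragments.bed")
  utils::write.table(truth$fragments[, c("chrom", "start", "end", "frag_id")],
                     fb, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["fragments"] <- fb
  tc <- file.path(dir, "planted_counts.tsv")
  utils::write.table(truth$planted_counts, tc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["planted_counts"] <- tc
  ay <- file.path(dir, "anchors.yaml")
  yaml::write_yaml(lapply(seq_len(nrow(truth$anchors)), function(i)
    as.list(truth$anchors[i, ])), ay)
  paths["anchors"] <- ay
  invisible(paths)
}

# plain 4-line FASTQ records with dummy Sanger qualities
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
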