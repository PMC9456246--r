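#' In-silico restriction digestion
#'
#' Scans every chromosome for the primary-enzyme recognition motif
#' (HindIII `AAGCTT` by default, which cuts `A^AGCTT`, i.e. one base into
#' the site) and returns the restriction fragments between consecutive
#' cut positions and the chromosome ends. Overlapping motif occurrences
#' are all reported; cut positions are deduplicated and sorted. Ambiguity
#' codes in the sequence never match the motif. A chromosome with no site
#' yields one whole-chromosome fragment.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @param site recognition motif (uppercase ACGT), default `"AAGCTT"`.
#' @param cut_offset cut position within the site in bp (default 1,
#'   HindIII; DpnII `^GATC` would be 0).
#' @return A `fragment_map`: data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open bp), `index` (ordinal on the chromosome)
#'   and `frag_id`. Fragments tile each chromosome `[0, L)` exactly.
#'   Chromosome lengths, the motif and the offset are kept as attributes.
#' @export
digest_genome <- function(genome, site = "AAGCTT", cut_offset = 1) {
  stopifnot(nchar(site) >= 1)
  genome <- as_genome(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    L <- lens[i]
    m <- Biostrings::matchPattern(site, genome[[i]], fixed = TRUE)
    cuts <- sort(unique(Biostrings::start(m) - 1L + as.integer(cut_offset)))
    cuts <- cuts[cuts > 0L & cuts < L]
    bounds <- c(0L, cuts, L)
    k <- length(bounds) - 1L
    out[[i]] <- data.frame(chrom = names(genome)[i],
                           start = bounds[-length(bounds)],
                           end = bounds[-1],
                           index = seq_len(k))
  }
  frags <- do.call(rbind, out)
  frags$frag_id <- paste(frags$chrom, frags$index, sep = "_")
  rownames(frags) <- NULL
  attr(frags, "chrom_lengths") <- lens
  attr(frags, "site") <- site
  attr(frags, "cut_offset") <- as.integer(cut_offset)
  class(frags) <- c("fragment_map", "data.frame")
  frags
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    # keep only the first word of FASTA headers
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, character(1), 1)
    return(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a named character vector or a DNAStringSet")
}

#' Demultiplex bait-anchored 4C reads
#'
#' A 4C read is informative only when it contains the primary-enzyme
#' ligation site: the bait-derived prefix before the first site
#' occurrence identifies the anchor (it must begin with exactly one
#' anchor primer), and the subsequence after the site is the captured
#' contact. Reads are kept iff the site occurs at position >= 1 (0-based;
#' a non-empty prefix must precede it). Every rejection is categorised:
#' `no_site`, `unknown_anchor`, or `ambiguous` (prefix matching more than
#' one primer).
#'
#' @param reads character vector or `DNAStringSet` of read sequences
#'   (names become read ids).
#' @param anchors data.frame with columns `anchor_id` and `primer`
#'   (uppercase ACGT, mutually non-prefix).
#' @param site ligation-site motif (default `"AAGCTT"`).
#' @param include_site keep the site motif at the start of the captured
#'   sequence (default `FALSE`).
#' @return data.frame with columns `read_id`, `category`
#'   (`"classified"`, `"no_site"`, `"unknown_anchor"`, `"ambiguous"`),
#'   `anchor_id` and `captured`; per-category counts as
#'   `attr(, "counts")`.
#' @export
parse_reads <- function(reads, anchors, site = "AAGCTT", include_site = FALSE) {
  if (inherits(reads, "XStringSet")) {
    ids <- names(reads)
    reads <- as.character(reads)
  } else {
    ids <- names(reads)
  }
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  validate_anchors(anchors)
  pos <- regexpr(site, reads, fixed = TRUE)   # 1-based, -1 when absent
  category <- rep("no_site", length(reads))
  anchor_id <- rep(NA_character_, length(reads))
  captured <- rep(NA_character_, length(reads))
  has <- pos >= 2L
  if (any(has)) {
    prefix <- substr(reads[has], 1L, pos[has] - 1L)
    hit <- matrix(FALSE, sum(has), nrow(anchors))
    for (j in seq_len(nrow(anchors)))
      hit[, j] <- startsWith(prefix, anchors$primer[j])
    nhit <- rowSums(hit)
    cat_h <- ifelse(nhit == 0L, "unknown_anchor",
                    ifelse(nhit > 1L, "ambiguous", "classified"))
    category[has] <- cat_h
    one <- which(has)[nhit == 1L]
    if (length(one)) {
      anchor_id[one] <- anchors$anchor_id[apply(hit[nhit == 1L, , drop = FALSE], 1, which)]
      from <- if (include_site) pos[one] else pos[one] + nchar(site)
      captured[one] <- substr(reads[one], from, nchar(reads[one]))
    }
  }
  out <- data.frame(read_id = ids, category = category,
                    anchor_id = anchor_id, captured = captured,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(total = length(reads),
                           classified = sum(category == "classified"),
                           no_site = sum(category == "no_site"),
                           unknown_anchor = sum(category == "unknown_anchor"),
                           ambiguous = sum(category == "ambiguous"))
  out
}

validate_anchors <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("anchor_id", "primer") %in% names(anchors)),
            nrow(anchors) >= 1)
  if (!all(grepl("^[ACGT]+$", anchors$primer)))
    stop("anchor primers must be nonempty uppercase ACGT")
  if (nrow(anchors) > 1) {
    for (i in seq_len(nrow(anchors)))
      for (j in seq_len(nrow(anchors)))
        if (i != j && startsWith(anchors$primer[i], anchors$primer[j]))
          stop("anchor primers must be mutually non-prefix")
  }
  invisible(anchors)
}

#' Exact-match mapping of captured sequences to a genome
#'
#' Maps each captured sequence by the unique exact occurrence of its
#' first `min_len` bases, on either strand, emulating "uniquely mapped
#' reads" on synthetic genomes (externally produced alignments can be
#' substituted wherever mapped positions are consumed). The reported
#' position is the 0-based plus-strand coordinate of the capture's 5'
#' base: the leftmost matched base for a plus-strand hit, the rightmost
#' for a minus-strand hit. Captures with zero or multiple genome-wide
#' occurrences are unmapped.
#'
#' @param captured character vector of captured sequences (`NA` allowed).
#' @param genome named character vector or `DNAStringSet`.
#' @param min_len seed length in bp (default 20).
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`
#'   (`"+"`/`"-"`) and `status` (`"mapped"`, `"unmapped_short"`,
#'   `"unmapped_invalid"`, `"unmapped_zero"`, `"unmapped_multi"`).
#' @export
map_exact <- function(captured, genome, min_len = 20) {
  genome <- as_genome(genome)
  n <- length(captured)
  status <- rep("unmapped_zero", n)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  short <- is.na(captured) | nchar(captured) < min_len
  status[short] <- "unmapped_short"
  pref <- rep(NA_character_, n)
  pref[!short] <- substr(captured[!short], 1L, min_len)
  invalid <- !short & !grepl("^[ACGT]+$", pref)
  status[invalid] <- "unmapped_invalid"
  usable <- !short & !invalid
  if (!any(usable))
    return(data.frame(chrom = chrom, pos = pos, strand = strand, status = status))

  uq <- unique(pref[usable])
  counts <- integer(length(uq))
  hchrom <- rep(NA_character_, length(uq))
  hpos <- rep(NA_integer_, length(uq))
  hstrand <- rep(NA_character_, length(uq))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq))
  for (ci in seq_along(genome)) {
    sq <- genome[[ci]]
    L <- length(sq)
    for (str in c("+", "-")) {
      subject <- if (str == "+") sq else Biostrings::reverseComplement(sq)
      mi <- Biostrings::matchPDict(pd, subject)
      cnt <- S4Vectors::elementNROWS(mi)
      hits <- which(cnt > 0L)
      for (k in hits) {
        s1 <- Biostrings::start(mi[[k]])[1]
        if (counts[k] == 0L) {
          hchrom[k] <- names(genome)[ci]
          if (str == "+") {
            hpos[k] <- s1 - 1L
            hstrand[k] <- "+"
          } else {
            hpos[k] <- L - s1          # 0-based plus-strand coord of the 5' base
            hstrand[k] <- "-"
          }
        }
        counts[k] <- counts[k] + cnt[k]
      }
    }
  }
  m <- match(pref[usable], uq)
  cm <- counts[m]
  iu <- which(usable)
  mapped <- cm == 1L
  status[iu[mapped]] <- "mapped"
  status[iu[cm > 1L]] <- "unmapped_multi"
  status[iu[cm == 0L]] <- "unmapped_zero"
  chrom[iu[mapped]] <- hchrom[m][mapped]
  pos[iu[mapped]] <- hpos[m][mapped]
  strand[iu[mapped]] <- hstrand[m][mapped]
  data.frame(chrom = chrom, pos = pos, strand = strand, status = status,
             stringsAsFactors = FALSE)
}

#' Assign mapped positions to restriction-fragment ends
#'
#' The raw 4C signal of a restriction fragment is the number of reads
#' mapping to its left or right end: a plus-strand position within
#' `end_tolerance` bp of a fragment start, or a minus-strand position
#' within `end_tolerance` of a fragment's last base, increments that
#' fragment. Positions matching no fragment end are discarded and
#' counted.
#'
#' @param mapped data.frame from [map_exact()] (or imported alignments
#'   with the same columns).
#' @param fragments a `fragment_map` from [digest_genome()].
#' @param end_tolerance bp slack for end trimming (default 4).
#' @return A `fragment_signal`: the fragment map with a `raw` count
#'   column; `attr(, "counts")` holds `assigned`, `end_miss` and
#'   `unmapped` totals.
#' @export
fragment_signal <- function(mapped, fragments, end_tolerance = 4) {
  stopifnot(inherits(fragments, "fragment_map"))
  raw <- integer(nrow(fragments))
  end_miss <- 0L
  ok <- which(!is.na(mapped$status) & mapped$status == "mapped")
  for (ci in unique(mapped$chrom[ok])) {
    fi <- which(fragments$chrom == ci)
    if (length(fi) == 0L) { end_miss <- end_miss + sum(mapped$chrom[ok] == ci); next }
    starts <- fragments$start[fi]
    ends <- fragments$end[fi]
    ri <- ok[mapped$chrom[ok] == ci]
    p <- mapped$pos[ri]
    s <- mapped$strand[ri]
    containing <- findInterval(p, starts)   # fragment whose [start, next start) holds p
    for (j in seq_along(ri)) {
      f <- containing[j]
      tgt <- NA_integer_
      if (s[j] == "+") {
        if (f >= 1L && p[j] - starts[f] <= end_tolerance) tgt <- f
        else if (f < length(fi) && starts[f + 1L] - p[j] <= end_tolerance) tgt <- f + 1L
      } else {
        if (f >= 1L && (ends[f] - 1L) - p[j] <= end_tolerance) tgt <- f
        else if (f > 1L && p[j] - (ends[f - 1L] - 1L) <= end_tolerance) tgt <- f - 1L
      }
      if (is.na(tgt)) end_miss <- end_miss + 1L
      else raw[fi[tgt]] <- raw[fi[tgt]] + 1L
    }
  }
  out <- fragments
  out$raw <- raw
  attr(out, "chrom_lengths") <- attr(fragments, "chrom_lengths")
  attr(out, "counts") <- c(assigned = sum(raw), end_miss = end_miss,
                           unmapped = sum(is.na(mapped$status) | mapped$status != "mapped"))
  class(out) <- c("fragment_signal", "fragment_map", "data.frame")
  out
}

#' Mask the bait fragment and its genomic neighbours
#'
#' Reads on the bait fragment and its two flanking fragments are
#' dominated by self-ligation and undigested template rather than real
#' contacts; standard 4C practice removes them before profiling. Disable
#' (flank < 0) for a strict counting mode that keeps every fragment.
#'
#' @param signals a `fragment_signal`.
#' @param bait_chrom,bait_index chromosome and fragment ordinal of the
#'   bait.
#' @param flank number of neighbouring fragments masked on each side
#'   (default 1).
#' @return The signal with masked fragments' `raw` set to 0; masked ids
#'   in `attr(, "masked")`.
#' @export
mask_bait_fragments <- function(signals, bait_chrom, bait_index, flank = 1) {
  if (flank < 0) return(signals)
  hit <- signals$chrom == bait_chrom &
    abs(signals$index - bait_index) <= flank
  masked <- signals$frag_id[hit]
  signals$raw[hit] <- 0L
  attr(signals, "masked") <- masked
  signals
}
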