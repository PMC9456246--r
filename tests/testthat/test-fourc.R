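test_that("digestion reproduces the worked HindIII example", {
  frags <- digest_genome(c(chrA = "NNAAGCTTNNNNAAGCTTNN"))
  expect_equal(frags$start, c(0, 3, 13))
  expect_equal(frags$end, c(3, 13, 20))
  expect_equal(frags$index, 1:3)
})

test_that("a siteless chromosome is one whole fragment", {
  frags <- digest_genome(c(chrA = "ACGTACGTAC"))
  expect_equal(nrow(frags), 1)
  expect_equal(c(frags$start, frags$end), c(0, 10))
})

test_that("overlapping motif occurrences are deduplicated and sorted", {
  frags <- digest_genome(c(chrA = "AAAA"), site = "AA", cut_offset = 0)
  # occurrences at 0,1,2 -> cuts 1,2 after dropping the chromosome start
  expect_equal(frags$start, c(0, 1, 2))
  expect_equal(frags$end, c(1, 2, 4))
  frags1 <- digest_genome(c(chrA = "AAAA"), site = "AA", cut_offset = 1)
  expect_equal(frags1$start, c(0, 1, 2, 3))
})

test_that("fragments tile every random chromosome without gaps or overlaps", {
  set.seed(23)
  for (i in 1:100) {
    L <- sample(50:400, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    frags <- digest_genome(c(chr = s))
    expect_equal(frags$start[1], 0)
    expect_equal(frags$end[nrow(frags)], L)
    if (nrow(frags) > 1)
      expect_equal(frags$start[-1], frags$end[-nrow(frags)])
    expect_true(all(frags$end > frags$start))
    expect_equal(sum(frags$end - frags$start), L)
  }
})

anchors2 <- data.frame(anchor_id = c("AML1_H", "CTRL_H"),
                       primer = c("CAGGTGAGTGTGGAGGTAGAGAG", "CCTGCCAACTTCGGTGTCC"))

test_that("read demultiplexing classifies by primer and ligation site", {
  reads <- c(good = paste0("CAGGTGAGTGTGGAGGTAGAGAG", "AAGCTT", "TGCATGCATGCA"),
             nosite = "CAGGTGAGTGTGGAGGTAGAGAGTTTTTTTT",
             unknown = paste0("GGGGGGGGGG", "AAGCTT", "ACGTACGT"),
             site_first = paste0("AAGCTT", "ACGTACGTACGT"))
  out <- parse_reads(reads, anchors2)
  expect_equal(out$category, c("classified", "no_site", "unknown_anchor", "no_site"))
  expect_equal(out$anchor_id[1], "AML1_H")
  expect_equal(out$captured[1], "TGCATGCATGCA")
  counts <- attr(out, "counts")
  expect_equal(sum(counts[-1]), unname(counts["total"]))

  with_site <- parse_reads(reads[1], anchors2, include_site = TRUE)
  expect_equal(with_site$captured[1], "AAGCTTTGCATGCATGCA")
})

test_that("prefix-overlapping primers are rejected", {
  bad <- data.frame(anchor_id = c("a", "b"), primer = c("ACGTACGT", "ACGT"))
  expect_error(parse_reads("ACGTAAGCTTACGT", bad), "non-prefix")
  expect_error(parse_reads("ACGT", data.frame(anchor_id = "a", primer = "acgt")),
               "uppercase")
})

test_that("exact mapping reports unique hits with strand-aware positions", {
  set.seed(29)
  chr <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  genome <- c(chr1 = chr)
  cap_plus <- substr(chr, 101, 130)          # 0-based 100..129
  tail25 <- substr(chr, 201, 230)            # 0-based 200..229
  cap_minus <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail25)))
  dup <- paste0(substr(chr, 1, 25), "")      # will be planted twice
  genome_dup <- c(chr1 = paste0(chr, dup))   # second copy of the first 25 bp

  out <- map_exact(c(cap_plus, cap_minus, "ACGT", NA), genome)
  expect_equal(out$status, c("mapped", "mapped", "unmapped_short", "unmapped_short"))
  expect_equal(out$pos[1], 100)
  expect_equal(out$strand[1], "+")
  # minus-strand position is the capture's 5' base on the plus strand
  expect_equal(out$pos[2], 229)
  expect_equal(out$strand[2], "-")

  dup_out <- map_exact(substr(chr, 1, 25), genome_dup)
  expect_equal(dup_out$status, "unmapped_multi")

  # brute-force string-search oracle on random captures
  for (i in 1:20) {
    a <- sample(1:570, 1)
    cap <- substr(chr, a, a + 24)
    rc <- sample(c(TRUE, FALSE), 1)
    if (rc) cap <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cap)))
    res <- map_exact(cap, genome, min_len = 25)
    nfwd <- length(gregexpr(substr(cap, 1, 25), chr, fixed = TRUE)[[1]])
    if (res$status == "mapped") {
      expect_equal(res$strand, if (rc) "-" else "+")
      expect_equal(res$pos, if (rc) a + 23 else a - 1)
    } else {
      expect_gt(nfwd, 1)
    }
  }
})

test_that("fragment signal counts left and right end hits only", {
  frags <- digest_genome(c(chr1 = paste0(strrep("C", 50), "AAGCTT",
                                         strrep("G", 44), "AAGCTT",
                                         strrep("T", 44))))
  # fragments: [0,51), [51,101), [101,150)
  mapped <- data.frame(
    chrom = rep("chr1", 7),
    pos = c(51, 52, 53, 100, 98, 75, 70),
    strand = c("+", "+", "+", "-", "-", "+", "-"),
    status = rep("mapped", 7))
  sig <- fragment_signal(mapped, frags, end_tolerance = 4)
  # 3 plus reads at the start of fragment 2, 2 minus at its end -> raw 5;
  # the mid-fragment read and the minus read at a left end are misses
  expect_equal(sig$raw, c(0, 5, 0))
  expect_equal(unname(attr(sig, "counts")["end_miss"]), 2)
  expect_equal(sum(sig$raw), unname(attr(sig, "counts")["assigned"]))
})

test_that("window profile equals the brute-force double loop", {
  set.seed(31)
  for (rep in 1:10) {
    L1 <- sample(3e3:8e3, 1); L2 <- sample(2e3:6e3, 1)
    g <- c(chrA = paste(sample(c("A", "C", "G", "T"), L1, TRUE), collapse = ""),
           chrB = paste(sample(c("A", "C", "G", "T"), L2, TRUE), collapse = ""))
    frags <- digest_genome(g, site = "GATC", cut_offset = 0)
    frags$raw <- rpois(nrow(frags), 0.7)
    class(frags) <- c("fragment_signal", class(frags))
    w <- sample(c(500, 1000, 1500), 1)
    got <- window_profile(frags, window = w)
    want <- brute_window_profile(frags, window = w)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("two signal-bearing midpoints in the first window count as 2", {
  frags <- structure(
    data.frame(chrom = "chr1", start = c(0, 150e3, 260e3),
               end = c(150e3, 260e3, 1e6), index = 1:3,
               frag_id = c("a", "b", "c"), raw = c(1, 3, 0)),
    chrom_lengths = c(chr1 = 1e6),
    class = c("fragment_signal", "fragment_map", "data.frame"))
  wp <- window_profile(frags, 5e5)
  expect_equal(wp$value, c(2, 0))   # raw-0 fragment contributes nothing
})

test_that("normalisation is scale invariant and merging averages replicates", {
  frags <- digest_genome(c(chr1 = paste(rep("ACGTAAGCTTACGTACGTAC", 50), collapse = "")))
  a <- frags; a$raw <- rpois(nrow(frags), 3) + 1
  class(a) <- c("fragment_signal", class(frags))
  b <- a; b$raw <- 2L * a$raw          # doubled library, same profile

  out <- normalize_and_merge(list(a, b), scale = 1e6, window = 100)
  expect_equal(out$r_min, 1)
  expect_equal(out$merged$normalized, a$raw * 1e6 / sum(a$raw))

  ident <- normalize_and_merge(list(a, a), window = 100)
  expect_equal(ident$r_min, 1)

  # independent noise: r equals a direct correlation recomputation
  set.seed(37)
  c1 <- a; c1$raw <- rpois(nrow(frags), 5)
  c2 <- a; c2$raw <- rpois(nrow(frags), 5)
  c1$raw[1] <- 1L; c2$raw[1] <- 1L     # guard against all-zero
  out2 <- normalize_and_merge(list(c1, c2), window = 100)
  p1 <- window_profile(c1, 100)$value
  p2 <- window_profile(c2, 100)$value
  expect_equal(out2$r_min, cor(p1, p2), tolerance = 1e-12)

  z <- a; z$raw <- 0L
  expect_error(normalize_and_merge(list(a, z)), "zero assigned")
})

test_that("trans fraction counts signal-bearing fragments off the bait chromosome", {
  sig <- structure(
    data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
               start = c(0, 100, 0, 100), end = c(100, 200, 100, 200),
               index = c(1, 2, 1, 2),
               frag_id = c("a", "b", "c", "d"), raw = c(2, 1, 0, 0)),
    chrom_lengths = c(chr1 = 200, chr2 = 200),
    class = c("fragment_signal", "fragment_map", "data.frame"))
  expect_equal(trans_fraction(sig, "chr1"), 0)
  sig$raw <- c(1, 1, 1, 1)
  expect_equal(trans_fraction(sig, "chr1"), 0.5)
  sig$raw <- rep(0L, 4)
  expect_error(trans_fraction(sig, "chr1"), "no signal")
})

test_that("partner enrichment detects total separation and ties give p = 1", {
  sig <- structure(
    data.frame(chrom = rep(c("chr1", "chr2", "chr3"), each = 10),
               start = rep(seq(0, 9e4, 1e4), 3),
               end = rep(seq(1e4, 1e5, 1e4), 3),
               index = rep(1:10, 3),
               frag_id = paste0("f", 1:30),
               raw = c(rep(5L, 10), rep(1L, 10), rep(0L, 10))),
    chrom_lengths = c(chr1 = 1e5, chr2 = 1e5, chr3 = 1e5),
    class = c("fragment_signal", "fragment_map", "data.frame"))
  genes <- data.frame(chrom = rep(c("chr2", "chr3"), each = 5),
                      start = rep(seq(0, 8e4, 2e4), 2),
                      end = rep(seq(2e4, 1e5, 2e4), 2),
                      name = paste0("g", 1:10))
  # all chr2 genes (signal-bearing) vs all chr3 genes (none):
  # every partner exceeds every background gene -> maximal U
  out <- partner_enrichment(sig, genes, paste0("g", 1:5), "chr1",
                            level = "fragment", alternative = "greater")
  expect_equal(unname(out$U), 25)
  expect_lt(out$p_value, 0.005)
  expect_equal(out$table$signal, c(rep(2, 5), rep(0, 5)))  # 2 fragments per 20-kb gene

  one <- partner_enrichment(sig, genes[c(1, 6), ], "g1", "chr1",
                            level = "window")
  expect_equal(one$p_value, 1)

  expect_error(partner_enrichment(sig, genes, character(0), "chr1"), "empty")
  expect_error(partner_enrichment(sig, genes, "nope", "chr1"), "subset")
})
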