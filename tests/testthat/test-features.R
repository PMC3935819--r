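test_that("neighbor profile counts flanks on the transcribed strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTTTTTTTTTCAGTTTTTTTTTT"))
  call <- merged_call(11)  # the A of CAG, flank C at -1, G at +1
  prof <- neighbor_profile(call, genome, flank = 1)
  expect_equal(prof$freq["C", "-1"], 1)
  expect_equal(prof$freq["A", "0"], 1)
  expect_equal(prof$freq["G", "1"], 1)
  expect_equal(colSums(prof$freq), c("-1" = 1, "0" = 1, "1" = 1))

  # complementing the genome and flipping the strand leaves it invariant
  rc <- Biostrings::reverseComplement(genome)
  call_rc <- merged_call(length(genome[[1]]) - 1 - 11, strand = "-")
  prof_rc <- neighbor_profile(call_rc, rc, flank = 1)
  expect_equal(prof_rc$freq, prof$freq)

  # off-contig flanks are excluded and counted
  two <- rbind(merged_call(11), merged_call(0))
  p2 <- neighbor_profile(two, genome, flank = 1)
  expect_equal(p2$n_excluded, 1L)
})

test_that("offset-0 purity holds for simulated A-to-G calls", {
  sim <- shared_sim()
  truth_ag <- sim$truth[sim$truth$rdd_type == "A-to-G", ]
  calls <- data.frame(contig = truth_ag$contig, pos = truth_ag$pos,
                      strand = truth_ag$strand, stringsAsFactors = FALSE)
  prof <- neighbor_profile(calls, sim$genome)
  # every planted A-to-G site sits on an adenosine of the transcribed strand
  expect_equal(prof$freq["A", "0"], 1)
  expect_equal(unname(colSums(prof$freq)), rep(1, 21))
  # the planted context bias: G depleted 5' and enriched 3'
  expect_lt(prof$freq["G", "-1"], 0.25)
  expect_gt(prof$freq["G", "1"], 0.25)
})

test_that("cluster fraction matches the all-pairs oracle", {
  calls <- data.frame(contig = "chr1", pos = c(100L, 110L, 500L))
  expect_equal(cluster_fraction(calls, 25), 2 / 3)
  expect_equal(cluster_fraction(calls[1, , drop = FALSE], 25), 0)
  # boundary: distance exactly 25 is inside the window
  expect_equal(cluster_fraction(data.frame(contig = "c", pos = c(0L, 25L))), 1)

  oracle <- function(pos, contig, w) {
    n <- length(pos)
    mean(vapply(seq_len(n), function(i)
      any(contig == contig[i] & abs(pos - pos[i]) <= w &
            seq_len(n) != i), logical(1)))
  }
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(2:200, 1)
    contig <- sample(c("c1", "c2"), n, replace = TRUE)
    pos <- sample.int(5000, n, replace = TRUE)
    calls <- data.frame(contig = contig, pos = pos)
    expect_equal(cluster_fraction(calls, 25), oracle(pos, contig, 25))
  }
})

test_that("inverted-repeat proximity uses a strict 1 kb bound", {
  repeats <- data.frame(contig = "chr1",
                        start = c(5000L, 6000L, 20000L),
                        end = c(5280L, 6280L, 20280L),
                        name = "Alu", strand = c("+", "-", "+"),
                        is_alu = TRUE,
                        pair_id = c("ip1", "ip1", NA),
                        stringsAsFactors = FALSE)
  calls <- rbind(merged_call(5100),              # inside the pair
                 merged_call(6280 + 999 - 1),    # 999 nt after the edge
                 merged_call(6280 + 1000 - 1),   # 1000 nt: far
                 merged_call(5000 - 999),        # 999 nt before the start
                 merged_call(20100))             # inside an unpaired Alu: far
  prox <- inverted_repeat_proximity(calls, repeats)
  expect_equal(prox$class,
               c("within", "near_lt_1kb", "far", "near_lt_1kb", "far"))
  expect_equal(sum(prox$fractions), 1)
  # no inverted repeats at all -> everything far, with a warning
  expect_warning(
    p0 <- inverted_repeat_proximity(calls, repeats[3, ]), "no inverted")
  expect_true(all(p0$class == "far"))
})

test_that("region assignment votes across transcripts", {
  gm <- gm_rows(
    gm_row("G1", "G1.T1", "exon", 0, 1000), gm_row("G1", "G1.T1", "CDS", 200, 800),
    gm_row("G1", "G1.T2", "exon", 0, 300), gm_row("G1", "G1.T2", "exon", 900, 1000),
    gm_row("G1", "G1.T2", "CDS", 200, 300))
  calls <- rbind(merged_call(250),   # CDS in both isoforms
                 merged_call(850),   # utr3 in T1, intron in T2 -> Mixed
                 merged_call(100),   # utr5 in both
                 merged_call(5000))  # intergenic
  lab <- assign_region(calls, gm)
  expect_equal(lab, c("CDS", "Mixed", "5'UTR", "intergenic"))
  # labels always partition the call set
  expect_true(all(lab %in% c("5'UTR", "CDS", "3'UTR", "intron",
                             "intergenic", "Mixed")))
  sim <- shared_sim()
  merged <- intersect_individuals(lapply(
    setNames(nm = sim$config$individuals), function(i)
      call_sites(sim$pileups[[i]]$dna, sim$pileups[[i]]$rna$control,
                 sim$genes, sim$repeats)))
  lab2 <- assign_region(merged, sim$genes)
  expect_equal(length(lab2), nrow(merged))
  expect_equal(sum(table(lab2)), nrow(merged))
})

test_that("hyperediting requires strictly more than the threshold", {
  gm <- gm_rows(gm_row("G1", "G1.T1", "exon", 0, 10000),
                gm_row("G2", "G2.T1", "exon", 20000, 30000))
  mk <- function(n, offset) do.call(rbind, lapply(seq_len(n), function(i)
    merged_call(offset + i * 10)))
  calls51 <- rbind(mk(51, 0), mk(50, 20000))
  h <- detect_hyperedited(calls51, gm, min_sites = 50)
  expect_equal(h$transcripts$transcript_id, "G1.T1")
  expect_equal(h$transcripts$n_sites, 51L)
  expect_equal(h$fraction, 51 / 101)
  h0 <- detect_hyperedited(calls51[0, ], gm)
  expect_equal(nrow(h0$transcripts), 0L)
  expect_equal(h0$fraction, 0)
})

test_that("the generator's hyperedited transcript is recovered from truth", {
  sim <- shared_sim()
  truth <- sim$truth
  calls <- data.frame(contig = truth$contig, pos = truth$pos,
                      rdd_type = truth$rdd_type, stringsAsFactors = FALSE)
  h <- detect_hyperedited(calls, sim$genes, min_sites = 50)
  hyper_gene <- unique(truth$gene_id[truth$class == "hyper"])
  # both isoforms of the planted gene share the span, so the planted gene
  # is exactly the reported gene set
  expect_equal(unique(h$transcripts$gene_id), hyper_gene)
  expect_true(all(h$transcripts$n_sites >= sim$config$hyper_sites))
})

test_that("motif scanning counts overlapping degenerate matches", {
  expect_equal(as.vector(scan_motifs("TATTTTT",
                                  list(motif_pattern("TA(T/A)TTTT")))), 1L)
  expect_equal(as.vector(scan_motifs("GGGG", are_patterns())),
               rep(0L, 4))
  expect_error(motif_pattern("TA(/)T"), "empty|bad")

  # brute-force oracle: expand alternatives and compare every substring
  expand_pattern <- function(pattern) {
    toks <- regmatches(pattern,
                       gregexpr("\\([ACGT/]+\\)|[ACGT]", pattern))[[1]]
    alts <- lapply(toks, function(t)
      if (startsWith(t, "(")) strsplit(gsub("[()]", "", t), "/")[[1]] else t)
    apply(do.call(expand.grid, alts), 1, paste, collapse = "")
  }
  brute_count <- function(seq, pattern) {
    words <- expand_pattern(pattern)
    k <- nchar(words[1])
    if (nchar(seq) < k) return(0L)
    sum(vapply(seq_len(nchar(seq) - k + 1), function(i)
      substr(seq, i, i + k - 1) %in% words, logical(1)))
  }
  expect_equal(as.vector(scan_motifs("TATTTTATTTT",
                                  list(motif_pattern("TA(T/A)TTTT")))),
               brute_count("TATTTTATTTT", "TA(T/A)TTTT"))
  set.seed(31)
  pats <- c("TA(T/A)TTTT", "(T/A)TTTA", "(T/C)TTTA", "ATTT(T/C)")
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    got <- scan_motifs(s, lapply(pats, motif_pattern))
    want <- vapply(pats, function(p) brute_count(s, p), integer(1))
    expect_equal(as.vector(got), unname(want))
  }
})

test_that("motif enrichment reproduces exact hypergeometric odds", {
  # identical proportions: odds ratio 1
  t_eq <- matrix(c(30, 70, 30, 70), 2, byrow = TRUE)
  res <- overlap_enrichment(t_eq)
  expect_equal(res$odds_ratio, 1)
  expect_gt(res$p_value, 0.99)
  # [[8,2],[2,8]] -> odds ratio 16; p from explicit hypergeometric sums
  t1 <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  res1 <- overlap_enrichment(t1)
  expect_equal(res1$odds_ratio, 16)
  pg <- sum(vapply(0:10, function(k) {
    p <- stats::dhyper(k, 10, 10, 10)
    if (p <= stats::dhyper(8, 10, 10, 10) + 1e-7) p else 0
  }, numeric(1)))
  expect_equal(res1$fisher_p, pg, tolerance = 1e-10)

  # sequence-level wrapper builds the presence table itself
  target <- c("TTTATTTTA", "GGTATTTTT", "CCTAATTTTC")
  control <- c("GGGG", "CCCC", "GCGC", "TATTTTT")
  e <- motif_enrichment(target, control, "TA(T/A)TTTT")
  expect_equal(unname(e$table[1, ]), c(2, 1))
  expect_equal(unname(e$table[2, ]), c(1, 3))
})
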