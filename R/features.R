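#' Neighbor-base composition around sites of one RDD type
#'
#' Computes, for offsets -flank..+flank relative to each site, the
#' frequency of each base among the flanking sequences, on the transcribed
#' strand: minus-strand sites contribute reverse-complemented flanks. This
#' is the profile in which A-to-G editing shows its hallmark 5'-G depletion
#' and 3'-G enrichment. Sites whose flanks run off the contig are excluded
#' and counted.
#'
#' @param calls Call data.frame, typically of a single `rdd_type`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param flank Number of nucleotides on each side (default 10).
#' @return List of class `neighbor_profile`: `freq` (4 x (2*flank+1)
#'   matrix, rows A,C,G,T, columns offsets), `n_used`, `n_excluded`.
#' @export
neighbor_profile <- function(calls, genome, flank = 10L) {
  if (nrow(calls) == 0) stop_rdd("neighbor_profile: no calls")
  widths <- setNames(Biostrings::width(genome), names(genome))
  ok <- calls$pos - flank >= 0 &
    calls$pos + flank < widths[calls$contig] &
    calls$contig %in% names(genome)
  used <- calls[ok, , drop = FALSE]
  if (nrow(used) == 0) stop_rdd("neighbor_profile: all flanks off-contig")
  seqs <- character(nrow(used))
  for (ctg in unique(used$contig)) {
    i <- used$contig == ctg
    seqs[i] <- substring(as.character(genome[[ctg]]),
                         used$pos[i] - flank + 1L, used$pos[i] + flank + 1L)
  }
  minus <- used$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  mat <- matrix(unlist(strsplit(seqs, "")), ncol = 2L * flank + 1L,
                byrow = TRUE)
  freq <- apply(mat, 2, function(col)
    table(factor(col, levels = ALLELES)) / length(col))
  dimnames(freq) <- list(ALLELES, as.character(seq(-flank, flank)))
  structure(list(freq = freq, n_used = nrow(used),
                 n_excluded = sum(!ok), flank = flank),
            class = "neighbor_profile")
}

#' Fraction of sites with a same-set neighbor within a window
#'
#' Center-to-center distance, inclusive (`<= window` nt), within the same
#' call set and contig.
#'
#' @param calls Call data.frame.
#' @param window Distance in nt (default 25).
#' @return Fraction of sites having at least one neighbor within the
#'   window (0 for fewer than two sites).
#' @export
cluster_fraction <- function(calls, window = 25L) {
  if (nrow(calls) < 2) return(0)
  clustered <- 0L
  for (p in split(calls$pos, calls$contig)) {
    p <- sort(p)
    d_prev <- c(Inf, diff(p))
    d_next <- c(diff(p), Inf)
    clustered <- clustered + sum(d_prev <= window | d_next <= window)
  }
  clustered / nrow(calls)
}

#' Classify sites by proximity to inverted repeats
#'
#' Inverted repeats are the repeat intervals carrying an
#' `inverted-pair` id. A site inside such an interval is `within`; a site
#' whose distance to the nearest edge is below `near_limit` nt is
#' `near_lt_1kb`; everything else is `far`. Distance is measured in
#' nucleotides from the site to the closest interval base (a site directly
#' adjacent to an interval is 1 nt away).
#'
#' @param calls Call data.frame.
#' @param repeats Repeat annotation (see [read_repeats()]).
#' @param near_limit Strict upper bound in nt for `near` (default 1000).
#' @return List: `class` (character per call), `fractions` (named numeric
#'   over the three classes, summing to 1).
#' @export
inverted_repeat_proximity <- function(calls, repeats, near_limit = 1000L) {
  n <- nrow(calls)
  inv <- repeats[!is.na(repeats$pair_id), , drop = FALSE]
  if (nrow(inv) == 0) {
    warning("no inverted repeats in annotation; all sites classified 'far'")
    cls <- rep("far", n)
  } else {
    q <- gr_pos(calls$contig, calls$pos)
    s <- gr0(inv$contig, inv$start, inv$end)
    within <- GenomicRanges::countOverlaps(q, s) > 0
    dist <- rep(Inf, n)
    dtn <- GenomicRanges::distanceToNearest(q, s)
    dist[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    cls <- ifelse(within, "within",
                  ifelse(dist + 1 < near_limit, "near_lt_1kb", "far"))
  }
  fr <- table(factor(cls, levels = c("within", "near_lt_1kb", "far"))) /
    max(n, 1L)
  list(class = cls, fractions = c(fr))
}

REGION_LABELS <- c("5'UTR", "CDS", "3'UTR", "intron", "intergenic", "Mixed")

#' Assign each site to a genic region
#'
#' Per overlapping transcript the site gets a label by containment
#' (CDS, 5'UTR, 3'UTR or intron); across all transcripts covering the
#' site, a unanimous label is kept, disagreement (including exons of
#' non-coding transcripts, whose annotation is ambiguous) yields `Mixed`,
#' and sites outside every transcript are `intergenic`.
#'
#' @param calls Call data.frame.
#' @param genes A `gene_models` table.
#' @return Character vector of labels (one of
#'   `r paste(REGION_LABELS, collapse = ", ")`), one per call.
#' @export
assign_region <- function(calls, genes) {
  n <- nrow(calls)
  if (n == 0) return(character(0))
  reg <- transcript_regions(genes)
  lab_map <- c(utr5 = "5'UTR", CDS = "CDS", utr3 = "3'UTR",
               intron = "intron", noncoding_exon = "noncoding_exon")
  hits <- GenomicRanges::findOverlaps(gr_pos(calls$contig, calls$pos),
                                      gr0(reg$contig, reg$start, reg$end))
  out <- rep("intergenic", n)
  hl <- split(lab_map[reg$region[S4Vectors::subjectHits(hits)]],
              S4Vectors::queryHits(hits))
  for (qi in names(hl)) {
    u <- unique(hl[[qi]])
    out[as.integer(qi)] <-
      if (length(u) == 1 && u %in% REGION_LABELS) u else "Mixed"
  }
  out
}

#' Detect hyperedited transcripts
#'
#' Transcripts carrying strictly more than `min_sites` A-to-G calls within
#' their span, sorted by site count descending, together with the fraction
#' of all A-to-G sites that fall in such transcripts.
#'
#' @param calls Call data.frame.
#' @param genes A `gene_models` table.
#' @param min_sites Strict lower bound on sites per transcript (default 50).
#' @return List: `transcripts` (data.frame `transcript_id`, `gene_id`,
#'   `n_sites`), `fraction` (of A-to-G sites inside reported transcripts).
#' @export
detect_hyperedited <- function(calls, genes, min_sites = 50L) {
  ag <- calls[calls$rdd_type == "A-to-G", , drop = FALSE]
  empty <- list(transcripts = data.frame(transcript_id = character(),
                                         gene_id = character(),
                                         n_sites = integer(),
                                         stringsAsFactors = FALSE),
                fraction = 0)
  if (nrow(ag) == 0) return(empty)
  sp <- transcript_spans(genes)
  hits <- GenomicRanges::findOverlaps(gr_pos(ag$contig, ag$pos),
                                      gr0(sp$contig, sp$start, sp$end))
  cnt <- table(S4Vectors::subjectHits(hits))
  keep <- as.integer(names(cnt)[cnt > min_sites])
  if (length(keep) == 0) return(empty)
  df <- data.frame(transcript_id = sp$transcript_id[keep],
                   gene_id = sp$gene_id[keep],
                   n_sites = as.integer(cnt[as.character(keep)]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_sites, df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  in_hyper <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) %in% keep]
  list(transcripts = df, fraction = length(unique(in_hyper)) / nrow(ag))
}

#' Define a degenerate motif pattern
#'
#' Patterns are written with parenthesized alternatives, e.g. the HuR
#' AU-rich element `"TA(T/A)TTTT"`. `U` is mapped to `T`. Internally the
#' pattern is converted to an IUPAC string matched with [Biostrings].
#'
#' @param pattern Pattern string.
#' @param name Optional name (defaults to the pattern string).
#' @return A list of class `motif_pattern` with `name`, `pattern` and the
#'   equivalent `iupac` string.
#' @export
motif_pattern <- function(pattern, name = pattern) {
  p <- chartr("u", "T", chartr("U", "T", toupper(pattern)))
  toks <- regmatches(p, gregexpr("\\([ACGT/]*\\)|[ACGT]", p))[[1]]
  if (sum(nchar(toks)) != nchar(p))
    stop_rdd("motif pattern '%s': unparseable characters", pattern)
  code_of <- function(set) {
    if (length(set) == 0)
      stop_rdd("motif pattern '%s': empty alternative set", pattern)
    key <- paste(sort(unique(set)), collapse = "")
    code <- names(Biostrings::IUPAC_CODE_MAP)[
      Biostrings::IUPAC_CODE_MAP == key]
    if (length(code) == 0)
      stop_rdd("motif pattern '%s': bad alternative set (%s)", pattern, key)
    code
  }
  iupac <- vapply(toks, function(t) {
    if (startsWith(t, "(")) {
      set <- strsplit(gsub("[()]", "", t), "/", fixed = TRUE)[[1]]
      code_of(set[nchar(set) > 0])
    } else t
  }, character(1))
  structure(list(name = name, pattern = pattern,
                 iupac = paste(iupac, collapse = "")),
            class = "motif_pattern")
}

#' The AU-rich element (ARE) patterns scanned by default
#'
#' The HuR-binding motif `TA(T/A)TTTT` and the three further HuR
#' recognition elements `(U/A)UUUA`, `(U/C)UUUA`, `AUUU(U/C)` in DNA
#' alphabet.
#'
#' @return Named list of [motif_pattern()] objects.
#' @export
are_patterns <- function() {
  list(HuR_TAWTTTT = motif_pattern("TA(T/A)TTTT", "HuR_TAWTTTT"),
       WTTTA = motif_pattern("(T/A)TTTA", "WTTTA"),
       YTTTA = motif_pattern("(T/C)TTTA", "YTTTA"),
       ATTTY = motif_pattern("ATTT(T/C)", "ATTTY"))
}

as_dna_set <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(as.character(seqs))))
}

#' Count motif occurrences in sequences
#'
#' Overlapping occurrences are counted on the given strand of each
#' sequence.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] (RNA `U`
#'   accepted and mapped to `T`).
#' @param patterns List of [motif_pattern()] objects (or pattern strings);
#'   defaults to [are_patterns()].
#' @return Named integer vector of total occurrence counts per pattern,
#'   with the per-sequence count matrix as attribute `"per_sequence"`.
#' @export
scan_motifs <- function(seqs, patterns = are_patterns()) {
  seqs <- as_dna_set(seqs)
  patterns <- lapply(patterns, function(p)
    if (inherits(p, "motif_pattern")) p else motif_pattern(p))
  nm <- vapply(patterns, `[[`, character(1), "name")
  per <- vapply(patterns, function(p)
    Biostrings::vcountPattern(p$iupac, seqs, fixed = FALSE),
    integer(length(seqs)))
  per <- matrix(per, nrow = length(seqs), dimnames = list(names(seqs), nm))
  structure(setNames(as.integer(colSums(per)), nm), per_sequence = per)
}

#' Test motif enrichment in target vs control sequences
#'
#' Builds the 2x2 presence table (target/control x has at least one
#' occurrence / none) and tests it with a 1-df chi-square (and Fisher's
#' exact test); the odds ratio uses the Haldane 0.5 correction when a cell
#' is zero. A degenerate table (all sequences in one column) yields p = 1
#' with a warning.
#'
#' @param target_seqs,control_seqs Sequence sets (character or
#'   [Biostrings::DNAStringSet]).
#' @param pattern A [motif_pattern()] or pattern string.
#' @return List: `table`, `chisq_stat`, `p_value` (chi-square),
#'   `fisher_p`, `odds_ratio`, `proportions` (fraction with the motif per
#'   row).
#' @export
motif_enrichment <- function(target_seqs, control_seqs, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  has <- function(seqs) {
    cnt <- attr(scan_motifs(seqs, list(pattern)), "per_sequence")
    sum(cnt[, 1] >= 1)
  }
  nt <- length(as_dna_set(target_seqs)); nc <- length(as_dna_set(control_seqs))
  if (nt == 0 || nc == 0) stop_rdd("motif_enrichment: empty sequence set")
  ht <- has(target_seqs); hc <- has(control_seqs)
  tab <- matrix(c(ht, nt - ht, hc, nc - hc), nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "control"), c("has", "none")))
  res <- overlap_enrichment(tab)
  c(list(pattern = pattern$name), res)
}
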