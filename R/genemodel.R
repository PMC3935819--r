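#' Transcript spans
#'
#' @param genes A `gene_models` table.
#' @return Data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `contig`, `start`, `end` (span of all exons, 0-based
#'   half-open), `strand`.
#' @export
transcript_spans <- function(genes) {
  ex <- genes[genes$type == "exon", , drop = FALSE]
  sp <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(s) {
    data.frame(transcript_id = s$transcript_id[1], gene_id = s$gene_id[1],
               contig = s$contig[1], start = min(s$start), end = max(s$end),
               strand = s$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Derive per-transcript genomic regions (5'UTR, CDS, 3'UTR, intron)
#'
#' UTRs are derived strand-aware from exons and CDS: exonic sequence
#' genomically upstream of the CDS span is the 5'UTR on plus-strand
#' transcripts and the 3'UTR on minus-strand ones. Gaps between exons
#' within the transcript span are introns. Exons of transcripts without
#' any CDS are labeled `noncoding_exon`.
#'
#' @param genes A `gene_models` table.
#' @return Data.frame with columns `transcript_id`, `gene_id`, `region`
#'   (`utr5`, `CDS`, `utr3`, `intron`, `noncoding_exon`), `contig`,
#'   `start`, `end`, `strand`.
#' @export
transcript_regions <- function(genes) {
  out <- lapply(split(as.data.frame(genes), genes$transcript_id), function(s) {
    exr <- IRanges::reduce(IRanges::IRanges(s$start[s$type == "exon"] + 1L,
                                            s$end[s$type == "exon"]))
    strand <- s$strand[1]
    span <- IRanges::IRanges(min(IRanges::start(exr)), max(IRanges::end(exr)))
    introns <- IRanges::setdiff(span, exr)
    pieces <- list()
    add <- function(ir, region) {
      if (length(ir) == 0) return()
      pieces[[length(pieces) + 1]] <<- data.frame(
        transcript_id = s$transcript_id[1], gene_id = s$gene_id[1],
        region = region, contig = s$contig[1],
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
        strand = strand, stringsAsFactors = FALSE)
    }
    add(introns, "intron")
    has_cds <- any(s$type == "CDS")
    if (!has_cds) {
      add(exr, "noncoding_exon")
    } else {
      cdr <- IRanges::reduce(IRanges::IRanges(s$start[s$type == "CDS"] + 1L,
                                              s$end[s$type == "CDS"]))
      cds_span <- IRanges::IRanges(min(IRanges::start(cdr)),
                                   max(IRanges::end(cdr)))
      add(cdr, "CDS")
      left <- IRanges::intersect(exr,
        IRanges::IRanges(IRanges::start(span),
                         IRanges::start(cds_span) - 1L))
      right <- IRanges::intersect(exr,
        IRanges::IRanges(IRanges::end(cds_span) + 1L, IRanges::end(span)))
      # exonic-but-not-CDS bases inside the CDS span are ambiguous; none are
      # produced by the bundled generator, label them noncoding_exon
      mid <- IRanges::setdiff(IRanges::intersect(exr, cds_span), cdr)
      add(mid, "noncoding_exon")
      if (strand == "+") { add(left, "utr5"); add(right, "utr3") }
      else { add(left, "utr3"); add(right, "utr5") }
    }
    do.call(rbind, pieces)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exonic length per transcript
#' @param genes A `gene_models` table.
#' @return Named integer vector, transcript id -> summed exon width (nt).
#' @export
transcript_lengths <- function(genes) {
  ex <- genes[genes$type == "exon", , drop = FALSE]
  vapply(split(ex, ex$transcript_id), function(s)
    sum(s$end - s$start), integer(1))
}

#' Merged exonic length per gene
#'
#' Union of exons over all transcripts of the gene.
#' @param genes A `gene_models` table.
#' @return Named integer vector, gene id -> merged exonic width (nt).
#' @export
gene_lengths <- function(genes) {
  ex <- genes[genes$type == "exon", , drop = FALSE]
  vapply(split(ex, ex$gene_id), function(s) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))))
  }, integer(1))
}

# transcript id -> gene id map
tx2gene <- function(genes) {
  sp <- transcript_spans(genes)
  setNames(sp$gene_id, sp$transcript_id)
}
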