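#' Read a pileup count table
#'
#' Parses the tab-separated pileup dialect used throughout the package:
#' one row per covered position with columns
#' `contig, position (1-based), sample, A, C, G, T, strand, unique`.
#' There is no header line. `strand` is the strand of origin of the RNA
#' reads from directional sequencing (`+`, `-`, or `*`/`.` for unknown);
#' DNA has no strand of origin, so DNA columns are always stored with
#' strand `*`. `unique` is `1`/`0` and flags positions whose reads mapped
#' uniquely under both aligners upstream.
#'
#' Positions are converted to the package-internal 0-based convention.
#'
#' @param path Path to the TSV file.
#' @param molecule `"DNA"` or `"RNA"`.
#' @return A data.frame with columns `contig`, `pos` (0-based), `sample`,
#'   `molecule`, `A`, `C`, `G`, `T`, `strand`, `unique`, in file order.
#' @export
read_pileup <- function(path, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (file.size(path) == 0) return(empty_pileup(molecule))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) != 9L)
    stop_rdd("pileup file '%s': expected 9 tab-separated columns, got %d",
             path, ncol(df))
  names(df) <- c("contig", "pos1", "sample", "A", "C", "G", "T",
                 "strand", "unique")
  num_cols <- c("pos1", "A", "C", "G", "T")
  for (cn in num_cols) {
    v <- suppressWarnings(as.integer(df[[cn]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_rdd("pileup file '%s', line %d: malformed value '%s' in column %s",
               path, bad[1], df[[cn]][bad[1]], cn)
    df[[cn]] <- v
  }
  neg <- which(df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0)
  if (length(neg))
    stop_rdd("pileup file '%s', line %d: negative allele count", path, neg[1])
  if (any(df$pos1 < 1L))
    stop_rdd("pileup file '%s': positions must be >= 1 (1-based)", path)
  strand <- df$strand
  strand[strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*")))
    stop_rdd("pileup file '%s': strand must be one of +, -, *, .", path)
  if (molecule == "DNA") strand <- rep("*", nrow(df))
  uq <- df$unique %in% c("1", "TRUE", "T", "true")
  data.frame(contig = df$contig, pos = df$pos1 - 1L, sample = df$sample,
             molecule = molecule, A = df$A, C = df$C, G = df$G, T = df$T,
             strand = strand, unique = uq, stringsAsFactors = FALSE)
}

empty_pileup <- function(molecule = "DNA") {
  data.frame(contig = character(), pos = integer(), sample = character(),
             molecule = character(), A = integer(), C = integer(),
             G = integer(), T = integer(), strand = character(),
             unique = logical(), stringsAsFactors = FALSE)
}

#' Write a pileup count table
#'
#' Inverse of [read_pileup()]: internal 0-based positions are written back
#' as 1-based.
#'
#' @param pileup Data.frame as returned by [read_pileup()].
#' @param path Output path.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.frame(pileup$contig, pileup$pos + 1L, pileup$sample,
                    pileup$A, pileup$C, pileup$G, pileup$T,
                    pileup$strand, as.integer(pileup$unique))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with uppercased sequences restricted
#'   to the alphabet A, C, G, T, N.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop_rdd("FASTA '%s' contains no sequences", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- colnames(freq)[!(colnames(freq) %in% c("A", "C", "G", "T", "N"))]
  if (any(freq[, extra, drop = FALSE] > 0))
    stop_rdd("FASTA '%s': alphabet outside {A,C,G,T,N}", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome to FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read repeat annotations from BED
#'
#' BED6 with the repeat family in the name field; a name beginning with
#' `"Alu"` marks the interval as an Alu element, and an optional
#' `;pair=<id>` suffix links the two members of an inverted-repeat pair
#' (e.g. `Alu;pair=ip3`). BED's 0-based half-open coordinates are kept
#' as-is.
#'
#' @param path BED file.
#' @return A data.frame with columns `contig`, `start`, `end`, `name`,
#'   `strand`, `is_alu`, `pair_id` (NA when unpaired).
#' @export
read_repeats <- function(path) {
  bed <- rtracklayer::import(path, format = "BED")
  name <- bed$name %||% rep("", length(bed))
  fam <- sub(";.*$", "", name)
  pair <- rep(NA_character_, length(bed))
  has_pair <- grepl(";pair=", name, fixed = TRUE)
  pair[has_pair] <- sub("^.*;pair=([^;]+).*$", "\\1", name[has_pair])
  rep_df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(bed)),
    start = GenomicRanges::start(bed) - 1L,
    end = GenomicRanges::end(bed),
    name = name,
    strand = as.character(GenomicRanges::strand(bed)),
    is_alu = grepl("^Alu", fam, ignore.case = TRUE),
    pair_id = pair,
    stringsAsFactors = FALSE)
  validate_repeats(rep_df)
  rep_df
}

validate_repeats <- function(rep_df) {
  if (any(rep_df$start >= rep_df$end))
    stop_rdd("repeat annotation: intervals must satisfy start < end")
  tab <- table(rep_df$pair_id[!is.na(rep_df$pair_id)])
  bad <- names(tab)[tab != 2L]
  if (length(bad))
    stop_rdd("repeat annotation: inverted-pair id(s) %s do not appear on exactly two intervals",
             paste(bad, collapse = ", "))
  invisible(rep_df)
}

#' Write repeat annotations to BED
#' @param repeats Data.frame as returned by [read_repeats()].
#' @param path Output path.
#' @export
write_repeats <- function(repeats, path) {
  name <- ifelse(repeats$is_alu, "Alu", "Rep")
  name <- ifelse(is.na(repeats$pair_id), name,
                 paste0(name, ";pair=", repeats$pair_id))
  out <- data.frame(repeats$contig, repeats$start, repeats$end, name,
                    0L, repeats$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads a GFF3 subset with `gene`, `mRNA`/`transcript`, `exon` and `CDS`
#' features linked by `ID`/`Parent`. GFF's 1-based closed intervals are
#' converted to internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @return A `gene_models` data.frame with one row per exon/CDS part:
#'   columns `gene_id`, `transcript_id`, `type` (`exon` or `CDS`),
#'   `contig`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(g$type)
  tx_sel <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(vapply(g$Parent[tx_sel], function(p) p[1] %||% NA_character_,
                             character(1)),
                      g$ID[tx_sel])
  part_sel <- type %in% c("exon", "CDS")
  parts <- g[part_sel]
  parent <- vapply(parts$Parent, function(p) p[1] %||% NA_character_, character(1))
  if (anyNA(parent))
    stop_rdd("gene models '%s': exon/CDS feature without Parent", path)
  strand <- as.character(GenomicRanges::strand(parts))
  if (any(strand == "*"))
    stop_rdd("gene models '%s': exon/CDS with unknown strand", path)
  gm <- data.frame(
    gene_id = unname(tx2gene[parent]),
    transcript_id = parent,
    type = as.character(parts$type),
    contig = as.character(GenomicRanges::seqnames(parts)),
    start = GenomicRanges::start(parts) - 1L,
    end = GenomicRanges::end(parts),
    strand = strand,
    stringsAsFactors = FALSE)
  gene_models(gm)
}

#' Construct a validated gene-models table
#'
#' @param df Data.frame with columns `gene_id`, `transcript_id`, `type`
#'   (`exon`/`CDS`), `contig`, `start`, `end` (0-based half-open), `strand`.
#' @return The validated data.frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  req <- c("gene_id", "transcript_id", "type", "contig", "start", "end", "strand")
  if (!all(req %in% names(df)))
    stop_rdd("gene models: missing column(s) %s",
             paste(setdiff(req, names(df)), collapse = ", "))
  if (!all(df$type %in% c("exon", "CDS")))
    stop_rdd("gene models: type must be 'exon' or 'CDS'")
  if (!all(df$strand %in% c("+", "-")))
    stop_rdd("gene models: strand must be '+' or '-'")
  if (any(df$start >= df$end))
    stop_rdd("gene models: start must be < end")
  # every CDS base must lie inside an exon of the same transcript
  for (tx in unique(df$transcript_id[df$type == "CDS"])) {
    sub <- df[df$transcript_id == tx, ]
    ex <- IRanges::IRanges(sub$start[sub$type == "exon"] + 1L,
                           sub$end[sub$type == "exon"])
    cd <- IRanges::IRanges(sub$start[sub$type == "CDS"] + 1L,
                           sub$end[sub$type == "CDS"])
    if (sum(IRanges::width(IRanges::setdiff(cd, ex))) > 0)
      stop_rdd("gene models: CDS outside exons for transcript %s", tx)
    if (length(IRanges::reduce(ex)) != length(ex))
      stop_rdd("gene models: overlapping exons within transcript %s", tx)
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to GFF3
#' @param genes A `gene_models` table.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in unique(genes$gene_id)) {
    sub <- genes[genes$gene_id == gid, ]
    writeLines(sprintf("%s\trddscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       sub$contig[1], min(sub$start) + 1L, max(sub$end),
                       sub$strand[1], gid), con)
    for (tx in unique(sub$transcript_id)) {
      ts <- sub[sub$transcript_id == tx, ]
      writeLines(sprintf("%s\trddscope\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         ts$contig[1], min(ts$start) + 1L, max(ts$end),
                         ts$strand[1], tx, gid), con)
      for (i in seq_len(nrow(ts))) {
        writeLines(sprintf("%s\trddscope\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%s%d;Parent=%s",
                           ts$contig[i], ts$type[i], ts$start[i] + 1L, ts$end[i],
                           ts$strand[i], ifelse(ts$type[i] == "CDS", "0", "."),
                           tx, tolower(ts$type[i]), i, tx), con)
      }
    }
  }
  invisible(path)
}

SITE_COLS <- c("contig", "start", "end", "dna_allele", "rna_allele",
               "rdd_type", "strand", "level", "dna_cov", "rna_cov",
               "is_alu", "region", "individuals", "ind_levels",
               "tie", "strand_unknown")

#' Write a called-site table
#'
#' BED-like TSV with a header: one row per site, 0-based half-open
#' single-base intervals, deterministically sorted by (contig, start).
#' Columns: contig, start, end, DNA allele and RNA variant allele (reference
#' strand), RDD type (transcribed strand), strand used, RDD level, DNA and
#' RNA coverage, Alu flag, region label, supporting individuals and their
#' levels, tie and strand-unknown flags.
#'
#' @param calls Call table as produced by [call_sites()] or
#'   [intersect_individuals()].
#' @param path Output path.
#' @export
write_site_table <- function(calls, path) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  out <- data.frame(
    contig = calls$contig %||% character(0),
    start = calls$pos, end = calls$pos + 1L,
    dna_allele = calls$dna_allele, rna_allele = calls$rna_allele,
    rdd_type = calls$rdd_type, strand = calls$strand,
    level = calls$level, dna_cov = calls$dna_cov, rna_cov = calls$rna_cov,
    is_alu = calls$is_alu,
    region = if (is.null(calls$region)) rep(".", n) else calls$region,
    individuals = if (is.null(calls$individuals)) calls$sample
                  else calls$individuals,
    ind_levels = if (is.null(calls$ind_levels))
                   paste0(calls$sample, "=", calls$level)
                 else calls$ind_levels,
    tie = if (is.null(calls$tie)) rep(FALSE, n) else calls$tie,
    strand_unknown = if (is.null(calls$strand_unknown)) rep(FALSE, n)
                     else calls$strand_unknown,
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a called-site table written by [write_site_table()]
#'
#' @param path Site-table TSV.
#' @return A merged-call data.frame (0-based `pos`).
#' @export
read_site_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "",
                   colClasses = c(contig = "character"))
  if (!all(SITE_COLS %in% names(df)))
    stop_rdd("site table '%s': missing column(s) %s", path,
             paste(setdiff(SITE_COLS, names(df)), collapse = ", "))
  data.frame(contig = df$contig, pos = df$start,
             dna_allele = df$dna_allele, rna_allele = df$rna_allele,
             rdd_type = df$rdd_type, strand = df$strand, level = df$level,
             dna_cov = df$dna_cov, rna_cov = df$rna_cov, is_alu = df$is_alu,
             region = df$region, individuals = df$individuals,
             ind_levels = df$ind_levels, tie = df$tie,
             strand_unknown = df$strand_unknown, stringsAsFactors = FALSE)
}

# parse "IND1=0.5;IND2=0.4" into a named numeric vector
parse_ind_levels <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)
  lapply(parts, function(p) {
    kv <- strsplit(p, "=", fixed = TRUE)
    setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
             vapply(kv, `[`, character(1), 1))
  })
}
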