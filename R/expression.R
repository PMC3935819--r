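#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = count * 1e9 / (length_nt * total_mapped)`.
#'
#' @param count Mapped read count of the unit.
#' @param length_nt Exonic length in nucleotides (> 0).
#' @param total_mapped Total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop_rdd("compute_rpkm: length must be > 0")
  if (any(total_mapped <= 0)) stop_rdd("compute_rpkm: total mapped must be > 0")
  count * 1e9 / (length_nt * total_mapped)
}

#' Per-transcript expression table
#'
#' Attaches gene ids, exonic lengths and RPKM to a raw count table.
#'
#' @param counts Data.frame with columns `transcript_id`, `count`, and
#'   optionally `total` (total mapped reads in the sample; defaults to
#'   `sum(count)`).
#' @param genes A `gene_models` table supplying transcript lengths and the
#'   transcript-to-gene map.
#' @return Data.frame `transcript_id`, `gene_id`, `length`, `count`,
#'   `total`, `rpkm`.
#' @export
transcript_expression <- function(counts, genes) {
  len <- transcript_lengths(genes)
  t2g <- tx2gene(genes)
  unknown <- setdiff(counts$transcript_id, names(len))
  if (length(unknown))
    stop_rdd("transcript_expression: unknown transcript(s) %s",
             paste(unknown, collapse = ", "))
  total <- counts$total %||% rep(sum(counts$count), nrow(counts))
  data.frame(transcript_id = counts$transcript_id,
             gene_id = unname(t2g[counts$transcript_id]),
             length = unname(len[counts$transcript_id]),
             count = counts$count, total = total,
             rpkm = compute_rpkm(counts$count,
                                 unname(len[counts$transcript_id]), total),
             stringsAsFactors = FALSE)
}

# aggregate transcript expression to genes: summed counts over the merged
# exonic length (not a sum of RPKMs)
gene_expression <- function(expr, genes) {
  glen <- gene_lengths(genes)
  agg <- aggregate(count ~ gene_id, data = expr, FUN = sum)
  total <- expr$total[1]
  data.frame(gene_id = agg$gene_id, length = unname(glen[agg$gene_id]),
             count = agg$count, total = total,
             rpkm = compute_rpkm(agg$count, unname(glen[agg$gene_id]), total),
             stringsAsFactors = FALSE)
}

#' Classify expression fold changes between control and knockdown
#'
#' Depth-normalized fold change per unit:
#' `((count_kd + pc)/total_kd) / ((count_ctrl + pc)/total_ctrl)` with
#' pseudocount `pc` guarding zero counts (transcript length cancels).
#' Units are `increased` at fold >= `fold_threshold`, `decreased` at
#' fold <= 1/`fold_threshold`, otherwise `unchanged`. Both transcript- and
#' gene-level classifications are produced (gene counts are summed over
#' isoforms).
#'
#' @param control,kd Expression tables from [transcript_expression()] on
#'   the same transcript universe.
#' @param genes The `gene_models` table.
#' @param fold_threshold Fold-change threshold (default 2).
#' @param pseudocount Added to each count (default 0.5).
#' @return List of class `expression_changes` with data.frames
#'   `transcripts` (`transcript_id`, `gene_id`, `fold`, `log2_fold`,
#'   `direction`) and `genes` (`gene_id`, `fold`, `log2_fold`,
#'   `direction`).
#' @export
classify_changes <- function(control, kd, genes, fold_threshold = 2.0,
                             pseudocount = 0.5) {
  if (fold_threshold <= 1) stop_rdd("fold_threshold must be > 1")
  if (!setequal(control$transcript_id, kd$transcript_id))
    stop_rdd("classify_changes: control and knockdown transcript universes differ")
  kd <- kd[match(control$transcript_id, kd$transcript_id), , drop = FALSE]
  fold_of <- function(cc, ct, kc, kt)
    ((kc + pseudocount) / kt) / ((cc + pseudocount) / ct)
  direction_of <- function(f)
    ifelse(f >= fold_threshold, "increased",
           ifelse(f <= 1 / fold_threshold, "decreased", "unchanged"))
  ft <- fold_of(control$count, control$total, kd$count, kd$total)
  tx <- data.frame(transcript_id = control$transcript_id,
                   gene_id = control$gene_id, fold = ft,
                   log2_fold = log2(ft), direction = direction_of(ft),
                   stringsAsFactors = FALSE)
  gc <- gene_expression(control, genes)
  gk <- gene_expression(kd, genes)
  gk <- gk[match(gc$gene_id, gk$gene_id), , drop = FALSE]
  fg <- fold_of(gc$count, gc$total, gk$count, gk$total)
  gn <- data.frame(gene_id = gc$gene_id, fold = fg, log2_fold = log2(fg),
                   direction = direction_of(fg), stringsAsFactors = FALSE)
  structure(list(transcripts = tx, genes = gn,
                 fold_threshold = fold_threshold), class = "expression_changes")
}

#' Detect isoform switching
#'
#' Genes in which at least two isoforms changed in opposite directions
#' (one classified `increased`, one `decreased`) while the total
#' gene-level expression stayed `unchanged` — the signature of a shift in
#' isoform usage that is invisible at the gene level.
#'
#' @param changes An `expression_changes` object from [classify_changes()].
#' @return Data.frame `gene_id`, `n_up`, `n_down`, `gene_direction`.
#' @export
detect_isoform_switching <- function(changes) {
  tx <- changes$transcripts
  per_gene <- split(tx$direction, tx$gene_id)
  cand <- names(per_gene)[vapply(per_gene, function(d)
    length(d) >= 2 && any(d == "increased") && any(d == "decreased"),
    logical(1))]
  gdir <- setNames(changes$genes$direction, changes$genes$gene_id)
  keep <- cand[gdir[cand] == "unchanged"]
  data.frame(gene_id = keep,
             n_up = vapply(per_gene[keep], function(d)
               sum(d == "increased"), integer(1)),
             n_down = vapply(per_gene[keep], function(d)
               sum(d == "decreased"), integer(1)),
             gene_direction = unname(gdir[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate editing change with expression change per gene
#'
#' Joins knockdown editing comparisons to gene-level expression fold
#' changes (sites mapped to genes by containment in transcript spans) and
#' reports the Pearson correlation between the per-gene mean relative
#' editing change and the log2 expression fold change, plus a contingency
#' summary of edited-vs-expression-changed status.
#'
#' @param comparisons Output of [compare_conditions()].
#' @param changes An `expression_changes` object.
#' @param genes The `gene_models` table (for the site-to-gene map).
#' @return List: `r` (Pearson, NA when undefined e.g. zero variance),
#'   `p_value`, `n_genes`, `contingency` (edited x changed table over all
#'   genes in `changes`).
#' @export
editing_expression_correlation <- function(comparisons, changes, genes) {
  ev <- comparisons[comparisons$category != "not_evaluable", , drop = FALSE]
  sp <- transcript_spans(genes)
  hits <- GenomicRanges::findOverlaps(gr_pos(ev$contig, ev$pos),
                                      gr0(sp$contig, sp$start, sp$end))
  site_gene <- data.frame(
    gene_id = sp$gene_id[S4Vectors::subjectHits(hits)],
    dlevel = ev$relative_change[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  site_gene <- site_gene[!duplicated(paste(site_gene$gene_id,
                                           S4Vectors::queryHits(hits))), ]
  ed <- aggregate(dlevel ~ gene_id, data = site_gene, FUN = mean)
  gn <- changes$genes
  joined <- merge(ed, gn[, c("gene_id", "log2_fold", "direction")],
                  by = "gene_id")
  joined <- joined[is.finite(joined$dlevel) & is.finite(joined$log2_fold), ]
  if (nrow(joined) < 3)
    stop_rdd("editing_expression_correlation: fewer than 3 joined genes")
  r <- p <- NA_real_
  if (sd(joined$dlevel) > 0 && sd(joined$log2_fold) > 0) {
    ct <- cor.test(joined$dlevel, joined$log2_fold, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  contingency <- table(edited = gn$gene_id %in% ed$gene_id,
                       changed = gn$direction != "unchanged")
  list(r = r, p_value = p, n_genes = nrow(joined), contingency = contingency)
}
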