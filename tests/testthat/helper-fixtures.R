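# shared in-code fixtures: pileup rows, tiny gene models, count helpers

pileup_row <- function(contig = "chr1", pos = 100L, sample = "IND1",
                       molecule = "DNA", A = 0L, C = 0L, G = 0L, T = 0L,
                       strand = "*", unique = TRUE) {
  data.frame(contig = contig, pos = pos, sample = sample,
             molecule = molecule, A = A, C = C, G = G, T = T,
             strand = strand, unique = unique, stringsAsFactors = FALSE)
}

# RNA pileup row realizing a given variant level at a given coverage
rna_row_level <- function(pos, ref, var, level, cov = 20L,
                          sample = "IND1", strand = "+", contig = "chr1") {
  counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
  nv <- as.integer(round(level * cov))
  counts[var] <- nv
  counts[ref] <- cov - nv
  pileup_row(contig, pos, sample, "RNA", counts[["A"]], counts[["C"]],
             counts[["G"]], counts[["T"]], strand, TRUE)
}

# one-gene model: exon 0..1000, CDS 200..800, so utr5 = 0..200 and
# utr3 = 800..1000 on the plus strand
tiny_gene <- function(gene_id = "G1", tx = "G1.T1", strand = "+",
                      offset = 0L, contig = "chr1") {
  gene_models(data.frame(
    gene_id = gene_id, transcript_id = tx,
    type = c("exon", "CDS"),
    contig = contig,
    start = c(0L, 200L) + offset, end = c(1000L, 800L) + offset,
    strand = strand, stringsAsFactors = FALSE))
}

# multi-part gene model from explicit rows
gm_rows <- function(...) gene_models(do.call(rbind, list(...)))

gm_row <- function(gene_id, tx, type, start, end, strand = "+",
                   contig = "chr1") {
  data.frame(gene_id = gene_id, transcript_id = tx, type = type,
             contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# merged-call row as produced by intersect_individuals()
merged_call <- function(pos, rna_allele = "G", dna_allele = "A",
                        rdd_type = "A-to-G", strand = "+",
                        levels = c(IND1 = 0.5, IND2 = 0.5),
                        contig = "chr1", is_alu = FALSE) {
  data.frame(contig = contig, pos = as.integer(pos),
             dna_allele = dna_allele, rna_allele = rna_allele,
             rdd_type = rdd_type, strand = strand, level = mean(levels),
             dna_cov = 20L, rna_cov = 20L, is_alu = is_alu,
             tie = FALSE, strand_unknown = FALSE,
             individuals = paste(names(levels), collapse = ","),
             ind_levels = paste(paste0(names(levels), "=", levels),
                                collapse = ";"),
             stringsAsFactors = FALSE)
}

# all compositions of total reads <= max_total over the four alleles
allele_compositions <- function(max_total) {
  g <- expand.grid(A = 0:max_total, C = 0:max_total, G = 0:max_total,
                   T = 0:max_total)
  m <- as.matrix(g[rowSums(g) <= max_total, ])
  storage.mode(m) <- "integer"
  m
}

# a small simulation shared by several test files (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(simulation_config(
        seed = 42, genome_length = 200000, n_genes = 20,
        n_adar1_only = 60, n_adar2_only = 12, n_shared = 24,
        n_non_ag = 12, n_hyper = 1, background_positions = 400))
    cache
  }
})
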