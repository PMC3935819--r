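#' Calling parameters for RDD/editing detection
#'
#' The stringent filter cascade: a site is called only when the DNA
#' genotype is homozygous (a single allele carries at least
#' `require_dna_concordance` of the DNA reads, 100% by default), both
#' molecules reach their minimum coverage, the variant-allele fraction in
#' RNA (the RDD level) reaches `min_rdd_level`, reads map uniquely when
#' `require_unique_mapping`, and — at the cohort stage — the site is found
#' in every individual when `require_all_individuals`.
#'
#' @param min_dna_coverage Minimum DNA read depth (default 10).
#' @param min_rna_coverage Minimum RNA read depth (default 10).
#' @param min_rdd_level Minimum variant fraction in RNA (default 0.10).
#' @param require_dna_concordance Minimum fraction of DNA reads on the
#'   genotype allele (default 1.00, i.e. full concordance).
#' @param require_unique_mapping Drop positions not flagged as uniquely
#'   mapped on both molecules (default TRUE).
#' @param require_all_individuals Keep only sites called in every
#'   individual at [intersect_individuals()] (default TRUE).
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(min_dna_coverage = 10L, min_rna_coverage = 10L,
                           min_rdd_level = 0.10,
                           require_dna_concordance = 1.00,
                           require_unique_mapping = TRUE,
                           require_all_individuals = TRUE) {
  if (min_rdd_level <= 0 || min_rdd_level > 1)
    stop_rdd("min_rdd_level must be in (0, 1]")
  if (min_dna_coverage < 1 || min_rna_coverage < 1)
    stop_rdd("coverage minima must be >= 1")
  if (require_dna_concordance <= 0 || require_dna_concordance > 1)
    stop_rdd("require_dna_concordance must be in (0, 1]")
  structure(list(min_dna_coverage = as.integer(min_dna_coverage),
                 min_rna_coverage = as.integer(min_rna_coverage),
                 min_rdd_level = min_rdd_level,
                 require_dna_concordance = require_dna_concordance,
                 require_unique_mapping = isTRUE(require_unique_mapping),
                 require_all_individuals = isTRUE(require_all_individuals)),
            class = "calling_params")
}

count_matrix <- function(pileup) {
  m <- as.matrix(pileup[, ALLELES])
  storage.mode(m) <- "integer"
  m
}

# vectorized DNA genotype: matrix n x 4 -> list(allele, reason)
dna_genotype_matrix <- function(counts, params) {
  tot <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  top_n <- counts[cbind(seq_len(nrow(counts)), top)]
  multi_max <- rowSums(counts == top_n) > 1L & top_n > 0L
  allele <- ALLELES[top]
  reason <- rep(NA_character_, nrow(counts))
  ok <- rep(TRUE, nrow(counts))
  conc_ok <- tot > 0 & top_n >= params$require_dna_concordance * tot & !multi_max
  reason[!conc_ok] <- "heterozygous_or_discordant"
  ok[!conc_ok] <- FALSE
  low <- tot < params$min_dna_coverage
  reason[low] <- "low_coverage"
  ok[low] <- FALSE
  nodata <- tot == 0L
  reason[nodata] <- "no_data"
  ok[nodata] <- FALSE
  allele[!ok] <- NA_character_
  list(allele = allele, reason = reason)
}

#' Call the DNA genotype of one pileup column
#'
#' A position is eligible for RDD calling only when a single allele carries
#' the required fraction (by default all) of at least `min_dna_coverage`
#' DNA reads. Heterozygous, discordant or under-covered positions are
#' rejected with a reason code and never produce calls.
#'
#' @param col One row of a DNA pileup data.frame (or a list with named
#'   counts `A`,`C`,`G`,`T`).
#' @param params A [calling_params()] object.
#' @return A list with `allele` (single character or NA) and `reason`
#'   (NA when called; `"low_coverage"`, `"heterozygous_or_discordant"` or
#'   `"no_data"` otherwise).
#' @export
call_dna_genotype <- function(col, params = calling_params()) {
  m <- matrix(as.integer(c(col$A, col$C, col$G, col$T)), nrow = 1,
              dimnames = list(NULL, ALLELES))
  if (any(m < 0)) stop_rdd("negative allele count")
  r <- dna_genotype_matrix(m, params)
  list(allele = r$allele[1], reason = r$reason[1])
}

# vectorized variant pick: counts n x 4, dna_allele char vector
rdd_variant_matrix <- function(counts, dna_allele) {
  n <- nrow(counts)
  tot <- rowSums(counts)
  masked <- counts
  masked[cbind(seq_len(n), match(dna_allele, ALLELES))] <- -1L
  vi <- max.col(masked, ties.method = "first")  # column order A<C<G<T
  vc <- masked[cbind(seq_len(n), vi)]
  tie <- rowSums(masked == vc) > 1L & vc > 0L
  variant <- ALLELES[vi]
  level <- ifelse(tot > 0, pmax(vc, 0L) / tot, 0)
  variant[vc <= 0L] <- NA_character_
  tie[vc <= 0L] <- FALSE
  list(variant = variant, level = level, tie = tie)
}

#' Compute the RDD level of one RNA pileup column
#'
#' The variant allele is the most frequent RNA allele different from the
#' DNA genotype; the RDD level (editing level for A-to-G) is its read count
#' divided by the total RNA reads at the position. Ties between two
#' non-DNA alleles are broken by the fixed allele order A < C < G < T and
#' flagged.
#'
#' @param col One row of an RNA pileup data.frame.
#' @param dna_allele The called DNA genotype allele.
#' @return A list with `variant` (character or NA when all reads match the
#'   DNA), `level` (fraction of total RNA reads) and `tie` (logical).
#' @export
compute_rdd_level <- function(col, dna_allele) {
  m <- matrix(as.integer(c(col$A, col$C, col$G, col$T)), nrow = 1,
              dimnames = list(NULL, ALLELES))
  if (sum(m) == 0) stop_rdd("compute_rdd_level: zero RNA coverage")
  r <- rdd_variant_matrix(m, dna_allele)
  list(variant = r$variant[1], level = r$level[1], tie = r$tie[1])
}

#' Classify an RDD into one of the 12 types on the transcribed strand
#'
#' On the minus strand both alleles are complemented before labeling, so
#' e.g. a reference-strand T-to-C difference in a minus-strand gene is an
#' A-to-G editing event. With unknown strand (`"*"`), plus-strand labeling
#' is used (callers flag such sites `strand_unknown`).
#'
#' @param dna_allele,variant_allele Reference-strand alleles.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return The type label, e.g. `"A-to-G"`.
#' @export
classify_rdd_type <- function(dna_allele, variant_allele, strand = "+") {
  if (any(dna_allele == variant_allele))
    stop_rdd("classify_rdd_type: identical DNA and variant alleles")
  d <- ifelse(strand == "-", COMPLEMENT[dna_allele], dna_allele)
  v <- ifelse(strand == "-", COMPLEMENT[variant_allele], variant_allele)
  unname(paste0(d, "-to-", v))
}

# per-site filter decision shared by call_sites() and tested exhaustively
# against a brute-force oracle: dna/rna are n x 4 integer count matrices.
decide_calls <- function(dna, rna, params) {
  g <- dna_genotype_matrix(dna, params)
  v <- rdd_variant_matrix(rna, ifelse(is.na(g$allele), "A", g$allele))
  rtot <- rowSums(rna)
  call <- !is.na(g$allele) &
    rtot >= params$min_rna_coverage &
    !is.na(v$variant) &
    v$level >= params$min_rdd_level
  data.frame(call = call, dna_allele = g$allele, reason = g$reason,
             variant = v$variant, level = v$level, tie = v$tie,
             dna_cov = rowSums(dna), rna_cov = rtot,
             stringsAsFactors = FALSE)
}

# transcribed strand per position from overlapping gene models:
# "+", "-", "both" or "none"
site_strand <- function(contig, pos, genes) {
  n <- length(pos)
  if (is.null(genes) || nrow(genes) == 0)
    return(rep("none", n))
  spans <- transcript_spans(genes)
  q <- gr_pos(contig, pos)
  hasp <- GenomicRanges::countOverlaps(
    q, gr0(spans$contig[spans$strand == "+"],
           spans$start[spans$strand == "+"],
           spans$end[spans$strand == "+"])) > 0
  hasm <- GenomicRanges::countOverlaps(
    q, gr0(spans$contig[spans$strand == "-"],
           spans$start[spans$strand == "-"],
           spans$end[spans$strand == "-"])) > 0
  out <- rep("none", n)
  out[hasp & !hasm] <- "+"
  out[hasm & !hasp] <- "-"
  out[hasp & hasm] <- "both"
  out
}

in_alu <- function(contig, pos, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0 || !any(repeats$is_alu))
    return(rep(FALSE, length(pos)))
  alu <- repeats[repeats$is_alu, ]
  GenomicRanges::countOverlaps(gr_pos(contig, pos),
                               gr0(alu$contig, alu$start, alu$end)) > 0
}

#' Call RDD/editing sites for one individual
#'
#' Joins DNA and RNA pileups of the same sample by (contig, position) and
#' emits a call wherever the full filter cascade passes: called homozygous
#' DNA genotype, RNA coverage at least `min_rna_coverage`, RDD level at
#' least `min_rdd_level`, and unique mapping on both molecules when
#' required. Each call is annotated with the transcribed strand from
#' overlapping gene models (falling back to the RNA strand of origin for
#' intergenic sites), the strand-adjusted 12-type label, and Alu
#' membership.
#'
#' @param dna,rna Pileup data.frames (see [read_pileup()]) for one sample.
#' @param genes A `gene_models` table or NULL.
#' @param repeats A repeat annotation data.frame (see [read_repeats()]) or
#'   NULL.
#' @param params A [calling_params()] object.
#' @return A data.frame of calls (one row per site) with columns `contig`,
#'   `pos`, `sample`, `dna_allele`, `rna_allele` (both reference strand),
#'   `rdd_type` (transcribed strand), `strand`, `level`, `dna_cov`,
#'   `rna_cov`, `is_alu`, `tie`, `strand_unknown`. Filter counters are
#'   attached as attribute `"counters"`.
#' @export
call_sites <- function(dna, rna, genes = NULL, repeats = NULL,
                       params = calling_params()) {
  stopifnot(all(dna$molecule == "DNA"), all(rna$molecule == "RNA"))
  sample_d <- unique(dna$sample); sample_r <- unique(rna$sample)
  if (length(sample_d) != 1 || length(sample_r) != 1 || sample_d != sample_r)
    stop_rdd("call_sites expects DNA and RNA pileups of one common sample (use intersect_individuals to combine individuals)")
  key_d <- paste(dna$contig, dna$pos)
  key_r <- paste(rna$contig, rna$pos)
  counters <- list(rna_positions = nrow(rna),
                   skipped_no_dna = sum(!(key_r %in% key_d)))
  idx <- match(key_r, key_d)
  keep <- !is.na(idx)
  rna2 <- rna[keep, , drop = FALSE]
  dna2 <- dna[idx[keep], , drop = FALSE]

  if (params$require_unique_mapping) {
    uq <- dna2$unique & rna2$unique
    counters$nonunique <- sum(!uq)
    rna2 <- rna2[uq, , drop = FALSE]
    dna2 <- dna2[uq, , drop = FALSE]
  } else counters$nonunique <- 0L

  if (nrow(rna2) == 0) {
    out <- empty_calls()
    attr(out, "counters") <- counters
    return(out)
  }

  dec <- decide_calls(count_matrix(dna2), count_matrix(rna2), params)
  counters$rejected_genotype <- sum(!is.na(dec$reason))
  counters$low_rna_coverage <- sum(is.na(dec$reason) &
                                     dec$rna_cov < params$min_rna_coverage)
  counters$below_level <- sum(is.na(dec$reason) &
                                dec$rna_cov >= params$min_rna_coverage &
                                !dec$call)
  sel <- which(dec$call)
  if (length(sel) == 0) {
    out <- empty_calls()
    counters$calls <- 0L
    attr(out, "counters") <- counters
    return(out)
  }
  contig <- rna2$contig[sel]; pos <- rna2$pos[sel]

  gstrand <- site_strand(contig, pos, genes)
  strand_used <- gstrand
  # intergenic: fall back to the RNA strand of origin from directional reads
  none <- gstrand == "none"
  strand_used[none] <- rna2$strand[sel][none]
  strand_unknown <- strand_used %in% c("both", "*")
  strand_used[strand_used == "both"] <- "*"

  lab_strand <- ifelse(strand_used == "-", "-", "+")
  out <- data.frame(
    contig = contig, pos = pos, sample = rna2$sample[sel],
    dna_allele = dec$dna_allele[sel], rna_allele = dec$variant[sel],
    rdd_type = classify_rdd_type(dec$dna_allele[sel], dec$variant[sel],
                                 lab_strand),
    strand = strand_used, level = dec$level[sel],
    dna_cov = dec$dna_cov[sel], rna_cov = dec$rna_cov[sel],
    is_alu = in_alu(contig, pos, repeats),
    tie = dec$tie[sel], strand_unknown = strand_unknown,
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  counters$calls <- nrow(out)
  attr(out, "counters") <- counters
  out
}

empty_calls <- function() {
  data.frame(contig = character(), pos = integer(), sample = character(),
             dna_allele = character(), rna_allele = character(),
             rdd_type = character(), strand = character(), level = numeric(),
             dna_cov = integer(), rna_cov = integer(), is_alu = logical(),
             tie = logical(), strand_unknown = logical(),
             stringsAsFactors = FALSE)
}

#' Keep sites called in every individual
#'
#' Sites are matched on (contig, position, RDD type): a position called
#' with different types in different individuals does not survive. The
#' merged record carries all supporting individuals, their per-individual
#' levels, and the mean level.
#'
#' @param calls_per_individual Named list (individual -> call data.frame
#'   from [call_sites()]).
#' @param params A [calling_params()] object; with
#'   `require_all_individuals = TRUE` (default) at least two individuals
#'   are required.
#' @return A merged call data.frame with columns as in [call_sites()] plus
#'   `individuals` (comma-separated) and `ind_levels`
#'   (`"IND1=0.5;IND2=0.4"`); `level` is the across-individual mean.
#' @export
intersect_individuals <- function(calls_per_individual,
                                  params = calling_params()) {
  inds <- names(calls_per_individual)
  if (is.null(inds) || any(inds == ""))
    stop_rdd("calls_per_individual must be a named list")
  if (params$require_all_individuals && length(inds) < 2)
    stop_rdd("cross-individual filtering requires at least two individuals")
  keys <- lapply(calls_per_individual, function(x)
    paste(x$contig, x$pos, x$rdd_type))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) {
    out <- empty_calls()
    out$sample <- NULL
    out$individuals <- character(0)
    out$ind_levels <- character(0)
    return(out)
  }
  base <- calls_per_individual[[1]]
  base <- base[match(common, keys[[1]]), , drop = FALSE]
  lv <- vapply(seq_along(inds), function(i) {
    calls_per_individual[[i]]$level[match(common, keys[[i]])]
  }, numeric(length(common)))
  lv <- matrix(lv, nrow = length(common))
  out <- base
  out$sample <- NULL
  out$level <- rowMeans(lv)
  out$individuals <- rep(paste(inds, collapse = ","), length(common))
  out$ind_levels <- apply(lv, 1, function(r)
    paste(paste0(inds, "=", r), collapse = ";"))
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition calls into Alu and non-Alu fractions
#'
#' @param calls A call data.frame.
#' @param repeats Repeat annotation; when NULL the calls' own `is_alu`
#'   column is used.
#' @return A list with `alu` and `non_alu` call data.frames and
#'   `type_counts`, a 12 x 2 integer matrix of per-type counts by
#'   partition.
#' @export
partition_by_repeat <- function(calls, repeats = NULL) {
  flag <- if (is.null(repeats)) calls$is_alu
          else in_alu(calls$contig, calls$pos, repeats)
  alu <- calls[flag, , drop = FALSE]
  non <- calls[!flag, , drop = FALSE]
  tc <- cbind(alu = table(factor(alu$rdd_type, levels = rdd_types())),
              non_alu = table(factor(non$rdd_type, levels = rdd_types())))
  list(alu = alu, non_alu = non, type_counts = tc)
}
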