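#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale emulation of the B-cell study design:
#' a gene-dense contig with Alu cassettes (half of them inverted pairs)
#' in introns and 3'UTRs, A-to-G sites planted preferentially in
#' Alu/inverted-repeat/3'UTR compartments with the 5'-G-depleted /
#' 3'-G-enriched neighbor context, per-site editing levels uniform on
#' 1%-99%, hyperedited transcripts with > 50 clustered sites, two
#' individuals sharing the truth but re-drawing read noise, binomial read
#' sampling with a 0.1% per-base error, and knockdown conditions that
#' scale editing levels per enzyme class (strong ADAR1 knockdown, partial
#' ADAR2 knockdown, and a compensatory boost of ADAR1-class sites under
#' ADAR2 knockdown).
#'
#' @param seed Integer master seed; every stream is derived from it.
#' @param contig Contig name.
#' @param genome_length Contig length in nt.
#' @param n_genes Number of genes (two isoforms each).
#' @param alu_density Probability that each of a gene's three Alu slots
#'   (first intron, second intron, 3'UTR) receives a cassette.
#' @param inverted_pair_fraction Probability that a first-intron cassette
#'   is an inverted pair rather than a single copy.
#' @param n_adar1_only,n_adar2_only,n_shared Planted A-to-G site counts
#'   per enzyme class.
#' @param n_non_ag Planted non-A-to-G RDD sites (types drawn from the
#'   other 11 labels, placed in CDS/5'UTR-weighted compartments).
#' @param alu_fraction Fraction of A-to-G sites placed inside Alu
#'   cassettes.
#' @param edited_gene_fraction Fraction of genes eligible to carry A-to-G
#'   sites; the rest stay unedited, giving the edited-vs-unedited
#'   transcript contrast used by the enrichment analyses.
#' @param level_range Per-site editing-level range (uniform draw).
#' @param neighbor_bias Probability that a planted A-to-G site is drawn
#'   from the 5'-non-G / 3'-G biased candidate subset.
#' @param n_hyper,hyper_sites Number of hyperedited transcripts and
#'   clustered A-to-G sites planted in each (> 50 for detection).
#' @param dna_depth,rna_depth DNA read depth (fixed) and mean RNA depth
#'   (Poisson).
#' @param error_rate Per-read probability of a uniformly random wrong
#'   base.
#' @param individuals Character vector of individual names (>= 2 for the
#'   cross-individual filter).
#' @param individual_specific_fraction Fraction of A-to-G sites present in
#'   only one individual (level 0 in the others).
#' @param nonunique_fraction Fraction of background positions flagged as
#'   not uniquely mapped.
#' @param adar1_kd_scale,adar2_kd_scale Multiplicative level scale applied
#'   to the targeted enzyme classes under the corresponding knockdown.
#' @param compensatory_boost Relative level increase of ADAR1-class sites
#'   under ADAR2 knockdown (capped at 1).
#' @param background_positions Number of unedited transcript positions
#'   included in the pileups.
#' @param expr_base_meanlog,expr_base_sdlog Log-normal parameters of the
#'   per-transcript base expression mean.
#' @param expr_n_up,expr_n_down Transcripts whose expression is multiplied
#'   by `expr_fold` / `1/expr_fold` under knockdown.
#' @param expr_fold Expression fold change of perturbed transcripts.
#' @param n_isoform_switch Genes planted with reciprocal (x2, x0.5)
#'   isoform multipliers and equal base means, so the gene total stays
#'   flat.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              contig = "chr1",
                              genome_length = 500000L,
                              n_genes = 40L,
                              alu_density = 0.9,
                              inverted_pair_fraction = 0.5,
                              n_adar1_only = 230L,
                              n_adar2_only = 26L,
                              n_shared = 84L,
                              n_non_ag = 24L,
                              alu_fraction = 0.85,
                              edited_gene_fraction = 0.6,
                              level_range = c(0.01, 0.99),
                              neighbor_bias = 0.8,
                              n_hyper = 2L,
                              hyper_sites = 60L,
                              dna_depth = 30L,
                              rna_depth = 50L,
                              error_rate = 0.001,
                              individuals = c("IND1", "IND2"),
                              individual_specific_fraction = 0,
                              nonunique_fraction = 0,
                              adar1_kd_scale = 0.1,
                              adar2_kd_scale = 0.5,
                              compensatory_boost = 0.3,
                              background_positions = 2000L,
                              expr_base_meanlog = log(200),
                              expr_base_sdlog = 1,
                              expr_n_up = 8L,
                              expr_n_down = 2L,
                              expr_fold = 2.0,
                              n_isoform_switch = 3L) {
  cfg <- as.list(environment())
  for (nm in c("seed", "genome_length", "n_genes", "n_adar1_only",
               "n_adar2_only", "n_shared", "n_non_ag", "n_hyper",
               "hyper_sites", "dna_depth", "rna_depth",
               "background_positions", "expr_n_up", "expr_n_down",
               "n_isoform_switch"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  probs <- c(alu_density, inverted_pair_fraction, alu_fraction,
             edited_gene_fraction,
             neighbor_bias, error_rate, individual_specific_fraction,
             nonunique_fraction, adar1_kd_scale, adar2_kd_scale)
  if (any(probs < 0 | probs > 1))
    stop_rdd("simulation_config: probabilities must lie in [0, 1]")
  if (dna_depth < 1 || rna_depth < 1)
    stop_rdd("simulation_config: depths must be >= 1")
  if (any(level_range < 0 | level_range > 1) ||
      level_range[1] > level_range[2])
    stop_rdd("simulation_config: level_range must be an increasing pair in [0, 1]")
  if (length(individuals) < 1 || anyDuplicated(individuals))
    stop_rdd("simulation_config: individuals must be distinct names")
  if (n_hyper > 0 && hyper_sites <= 0)
    stop_rdd("simulation_config: hyper_sites must be positive")
  structure(cfg, class = "simulation_config")
}

GENE_SLOT_MIN <- 9000L  # smallest per-gene slot the layout can host

#' Generate a synthetic genome with genes, Alu cassettes and inverted repeats
#'
#' Genes are laid out on alternating strands in equal slots along the
#' contig, each with three exons, a CDS, UTRs and two isoforms (the second
#' skips the middle exon). Alu-like cassettes (a fixed random 280-nt
#' consensus per simulation) overwrite intronic/3'UTR sequence; a
#' configurable fraction of first-intron cassettes are inverted pairs
#' (copy plus nearby reverse complement). Fully deterministic under the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `repeats`
#'   (data.frame as from [read_repeats()]), `genes` (`gene_models`).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  ng <- config$n_genes
  slot <- L %/% ng
  if (slot < GENE_SLOT_MIN)
    stop_rdd("genome too short: %d nt for %d genes (need >= %d nt per gene)",
             L, ng, GENE_SLOT_MIN)
  ref <- sample(ALLELES, L, replace = TRUE)
  alu_seq <- sample(ALLELES, 280L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))  # mildly A/T-rich cassette
  alu_rc <- rev(unname(COMPLEMENT[alu_seq]))

  gene_rows <- list(); rep_rows <- list(); pair_n <- 0L
  for (gi in seq_len(ng)) {
    g0 <- (gi - 1L) * slot + 500L
    span <- slot - 1000L
    strand <- if (gi %% 2L == 1L) "+" else "-"
    # layout in transcription-relative coordinates, then reflect for minus
    e1 <- c(0L, 400L)                       # 200 utr5 + 200 cds
    i2s <- span %/% 2L - 150L
    e2 <- c(i2s, i2s + 300L)                # cds
    e3 <- c(span - 800L, span)              # 200 cds + 600 utr3
    cds <- list(c(200L, 400L), e2, c(span - 800L, span - 600L))
    refl <- function(iv) if (strand == "+") iv else c(span - iv[2], span - iv[1])
    abs_iv <- function(iv) { iv <- refl(iv); c(g0 + iv[1], g0 + iv[2]) }
    ex <- lapply(list(e1, e2, e3), abs_iv)
    cd <- lapply(cds, abs_iv)
    gid <- sprintf("G%03d", gi)
    add_tx <- function(tid, exs, cdss) {
      lapply(seq_along(exs), function(k)
        data.frame(gene_id = gid, transcript_id = tid, type = "exon",
                   contig = config$contig, start = exs[[k]][1],
                   end = exs[[k]][2], strand = strand,
                   stringsAsFactors = FALSE)) -> a
      lapply(seq_along(cdss), function(k)
        data.frame(gene_id = gid, transcript_id = tid, type = "CDS",
                   contig = config$contig, start = cdss[[k]][1],
                   end = cdss[[k]][2], strand = strand,
                   stringsAsFactors = FALSE)) -> b
      c(a, b)
    }
    gene_rows <- c(gene_rows,
                   add_tx(paste0(gid, ".T1"), ex, cd),
                   add_tx(paste0(gid, ".T2"), ex[c(1, 3)], cd[c(1, 3)]))

    # Alu slots: first intron (possibly a pair), second intron, 3'UTR
    ord <- order(vapply(ex, `[`, numeric(1), 1))
    exo <- ex[ord]
    intr1 <- c(exo[[1]][2] + 50L, exo[[2]][1] - 50L)
    intr2 <- c(exo[[2]][2] + 50L, exo[[3]][1] - 50L)
    utr3 <- if (strand == "+") c(g0 + span - 600L, g0 + span)
            else c(g0, g0 + 600L)
    place <- function(window, rc = FALSE, pid = NA_character_) {
      w <- window[2] - window[1]
      if (w < 300L) return(NULL)
      s <- window[1] + sample.int(w - 280L, 1L)
      ref[(s + 1L):(s + 280L)] <<- if (rc) alu_rc else alu_seq
      data.frame(contig = config$contig, start = s, end = s + 280L,
                 name = "Alu", strand = if (rc) "-" else "+",
                 is_alu = TRUE, pair_id = pid, stringsAsFactors = FALSE)
    }
    if (runif(1) < config$alu_density) {
      if (runif(1) < config$inverted_pair_fraction) {
        pair_n <- pair_n + 1L
        pid <- sprintf("ip%03d", pair_n)
        mid <- (intr1[1] + intr1[2]) %/% 2L
        rep_rows <- c(rep_rows,
                      list(place(c(intr1[1], mid - 80L), FALSE, pid),
                           place(c(mid + 80L, intr1[2]), TRUE, pid)))
      } else {
        rep_rows <- c(rep_rows, list(place(intr1)))
      }
    }
    if (runif(1) < config$alu_density)
      rep_rows <- c(rep_rows, list(place(intr2)))
    if (runif(1) < config$alu_density * 0.5)
      rep_rows <- c(rep_rows, list(place(utr3)))
  }
  genes <- gene_models(do.call(rbind, gene_rows))
  repeats <- do.call(rbind, c(rep_rows, list(NULL)))
  if (is.null(repeats))
    repeats <- data.frame(contig = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character(), is_alu = logical(),
                          pair_id = character(), stringsAsFactors = FALSE)
  validate_repeats(repeats)
  genome <- Biostrings::DNAStringSet(setNames(paste(ref, collapse = ""),
                                              config$contig))
  list(genome = genome, repeats = repeats, genes = genes)
}

# positions (0-based) inside a set of intervals given as data.frame start/end
positions_in <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(integer(0))
  red <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  unlist(lapply(seq_along(red), function(i)
    seq(IRanges::start(red)[i] - 1L, IRanges::end(red)[i] - 1L)))
}

#' Plant RDD/editing sites into a synthetic genome
#'
#' A-to-G sites (classes `adar1_only`, `adar2_only`, `shared`, plus
#' clustered `hyper` sites) are placed on transcribed-strand adenosines,
#' preferentially inside Alu cassettes and otherwise in 3'UTR/intron
#' compartments, with a configurable preference for the 5'-non-G / 3'-G
#' neighbor context. Non-A-to-G RDDs are placed in CDS/5'UTR compartments
#' on bases matching their source allele. Each site draws an editing level
#' uniformly from `level_range` and per-condition levels from the enzyme
#' scale factors (ADAR1-class sites gain the compensatory boost under
#' ADAR2 knockdown).
#'
#' @param geno Output of [generate_genome()].
#' @param config The [simulation_config()].
#' @return The ground-truth ledger: one row per planted site with
#'   reference-strand alleles, type, class, per-condition true levels,
#'   transcript/gene, Alu and inverted-pair flags, and the owning
#'   individual (NA when shared).
#' @export
plant_sites <- function(geno, config) {
  set.seed(config$seed + 1L)
  ref <- strsplit(as.character(geno$genome[[1]]), "")[[1]]
  genes <- geno$genes
  repeats <- geno$repeats
  reg <- transcript_regions(genes)
  spans <- transcript_spans(genes)

  strand_at <- rep(NA_character_, length(ref))
  for (i in seq_len(nrow(spans)))
    strand_at[(spans$start[i] + 1L):spans$end[i]] <- spans$strand[i]

  # transcribed-strand base and neighbor-context test per reference position
  src_ok <- function(pos, base) {
    st <- strand_at[pos + 1L]
    ifelse(is.na(st), FALSE,
           ifelse(st == "+", ref[pos + 1L] == base,
                  ref[pos + 1L] == COMPLEMENT[base]))
  }
  ctx_ok <- function(pos) {
    st <- strand_at[pos + 1L]
    up <- ifelse(st == "+", ref[pos], ref[pos + 2L])
    dn <- ifelse(st == "+", ref[pos + 2L], ref[pos])
    ifelse(st == "+", up != "G" & dn == "G", up != "C" & dn == "C")
  }

  # A-to-G editing is confined to a seeded subset of "edited" genes so
  # that unedited transcripts exist as a contrast set
  gene_ids <- unique(spans$gene_id)
  n_edited <- max(1L, round(config$edited_gene_fraction * length(gene_ids)))
  edited_genes <- sort(sample(gene_ids, n_edited))
  ed_spans <- spans[spans$gene_id %in% edited_genes, , drop = FALSE]
  in_edited <- rep(FALSE, length(ref))
  for (i in seq_len(nrow(ed_spans)))
    in_edited[(ed_spans$start[i] + 1L):ed_spans$end[i]] <- TRUE

  alu_pos <- positions_in(repeats[repeats$is_alu, , drop = FALSE])
  genic <- !is.na(strand_at)
  alu_pos <- alu_pos[genic[alu_pos + 1L]]
  ag_alu <- alu_pos[in_edited[alu_pos + 1L]]
  ag_alu <- ag_alu[src_ok(ag_alu, "A")]
  soft <- positions_in(reg[reg$region %in% c("utr3", "intron"), , drop = FALSE])
  soft <- setdiff(soft, alu_pos)
  soft <- soft[in_edited[soft + 1L]]
  ag_soft <- soft[src_ok(soft, "A")]
  hard <- positions_in(reg[reg$region %in% c("utr5", "CDS"), , drop = FALSE])

  taken <- integer(0)
  draw_pool <- function(pool, n, label) {
    pool <- setdiff(pool, taken)
    biased <- pool[ctx_ok(pool)]
    out <- integer(0)
    n_b <- rbinom(1L, n, config$neighbor_bias)
    n_b <- min(n_b, length(biased))
    if (n_b > 0) out <- biased[sample.int(length(biased), n_b)]
    rest <- setdiff(pool, out)
    n_u <- n - length(out)
    if (n_u > length(rest))
      stop_rdd("plant_sites: compartment '%s' cannot host %d sites", label, n)
    if (n_u > 0) out <- c(out, rest[sample.int(length(rest), n_u)])
    taken <<- c(taken, out)
    sort(out)
  }
  draw_ag <- function(n, label) {
    n_alu <- rbinom(1L, n, config$alu_fraction)
    c(draw_pool(ag_alu, n_alu, paste0(label, "/Alu")),
      draw_pool(ag_soft, n - n_alu, paste0(label, "/non-Alu")))
  }

  classes <- list(adar1_only = config$n_adar1_only,
                  adar2_only = config$n_adar2_only,
                  shared = config$n_shared)
  site_rows <- list()
  add_sites <- function(pos, class, type) {
    if (length(pos) == 0) return()
    st <- strand_at[pos + 1L]
    src <- sub("-to-.*$", "", type)
    var <- sub("^.*-to-", "", type)
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      contig = names(geno$genome)[1], pos = pos, strand = st,
      dna_allele = ifelse(st == "+", src, COMPLEMENT[src]),
      rna_allele = ifelse(st == "+", var, COMPLEMENT[var]),
      rdd_type = type, class = class, stringsAsFactors = FALSE)
  }
  for (cl in names(classes))
    add_sites(draw_ag(classes[[cl]], cl), cl, "A-to-G")

  # hyperedited transcripts: clustered A-to-G sites inside one window
  hyper_tx <- character(0)
  if (config$n_hyper > 0) {
    t1 <- spans[grepl("\\.T1$", spans$transcript_id) &
                  spans$gene_id %in% edited_genes, , drop = FALSE]
    pick <- t1[sample.int(nrow(t1), config$n_hyper), , drop = FALSE]
    hyper_tx <- pick$transcript_id
    for (i in seq_len(nrow(pick))) {
      w0 <- pick$start[i] + 800L
      w1 <- min(pick$end[i], w0 + 2500L)
      win <- seq(w0, w1 - 1L)
      win <- win[src_ok(win, "A")]
      win <- setdiff(win, taken)
      if (length(win) < config$hyper_sites)
        stop_rdd("plant_sites: hyperedited window in %s cannot host %d sites",
                 pick$transcript_id[i], config$hyper_sites)
      pos <- sort(win[sample.int(length(win), config$hyper_sites)])
      taken <- c(taken, pos)
      add_sites(pos, "hyper", "A-to-G")
    }
  }

  if (config$n_non_ag > 0) {
    types <- sample(setdiff(rdd_types(), "A-to-G"), config$n_non_ag,
                    replace = TRUE)
    for (tp in unique(types)) {
      n_tp <- sum(types == tp)
      src <- sub("-to-.*$", "", tp)
      pool <- hard[src_ok(hard, src)]
      add_sites(draw_pool(pool, n_tp, paste0("CDS-5'UTR/", tp)), "non_ag", tp)
    }
  }

  truth <- do.call(rbind, c(site_rows, list(NULL)))
  if (is.null(truth)) truth <- data.frame()
  if (nrow(truth) > 0) {
    n <- nrow(truth)
    truth$level_control <- runif(n, config$level_range[1],
                                 config$level_range[2])
    a1 <- truth$class %in% c("adar1_only", "hyper")
    a2 <- truth$class == "adar2_only"
    sh <- truth$class == "shared"
    lc <- truth$level_control
    truth$level_ADAR1_KD <- ifelse(a1 | sh, lc * config$adar1_kd_scale, lc)
    truth$level_ADAR2_KD <- ifelse(a2 | sh, lc * config$adar2_kd_scale,
      ifelse(a1, pmin(1, lc * (1 + config$compensatory_boost)), lc))
    truth$level_double_KD <- ifelse(
      sh, lc * config$adar1_kd_scale * config$adar2_kd_scale,
      ifelse(a1, lc * config$adar1_kd_scale,
             ifelse(a2, lc * config$adar2_kd_scale, lc)))

    q <- gr_pos(truth$contig, truth$pos)
    truth$is_alu <- in_alu(truth$contig, truth$pos, repeats)
    inv <- repeats[!is.na(repeats$pair_id), , drop = FALSE]
    truth$in_inverted_pair <- GenomicRanges::countOverlaps(
      q, gr0(inv$contig, inv$start, inv$end)) > 0
    hits <- GenomicRanges::findOverlaps(q, gr0(spans$contig, spans$start,
                                               spans$end))
    first <- !duplicated(S4Vectors::queryHits(hits))
    truth$transcript_id <- NA_character_
    truth$transcript_id[S4Vectors::queryHits(hits)[first]] <-
      spans$transcript_id[S4Vectors::subjectHits(hits)[first]]
    truth$transcript_id[truth$class == "hyper"] <-
      rep(hyper_tx, each = config$hyper_sites)
    truth$gene_id <- unname(tx2gene(genes)[truth$transcript_id])
    truth$individual <- NA_character_
    is_ag <- truth$rdd_type == "A-to-G"
    priv <- is_ag & runif(n) < config$individual_specific_fraction
    truth$individual[priv] <- sample(config$individuals, sum(priv),
                                     replace = TRUE)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  }
  truth
}

cond_index <- function(condition) match(condition, KD_CONDITIONS)

# multinomial read draws with per-read uniform error to the other bases
draw_counts <- function(true_base, variant_base, p_variant, depth, eps) {
  n <- length(depth)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, ALLELES))
  ti <- match(true_base, ALLELES)
  vi <- match(variant_base, ALLELES)
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    m <- rep(0, 4L)
    p <- if (is.na(vi[i])) 0 else p_variant[i]
    m[ti[i]] <- 1 - p
    if (!is.na(vi[i])) m[vi[i]] <- m[vi[i]] + p
    # per-read error: a read keeps its base w.p. 1-eps, else lands
    # uniformly on one of the other three bases
    q <- m * (1 - eps) + eps / 3 * (1 - m)
    out[i, ] <- rmultinom(1L, depth[i], q / sum(q))
  }
  out
}

#' Simulate DNA and RNA pileups for one individual and condition
#'
#' DNA reads re-sample the (homozygous reference) genotype with the
#' per-read error rate; RNA reads are variant with probability equal to
#' the site's true level under the condition (0 at background positions
#' and at sites owned by another individual), again with sequencing
#' error. RNA depth is Poisson around `rna_depth`; DNA depth is fixed.
#' Pileups cover all planted sites plus the shared background positions.
#' Deterministic given config seed, condition and individual.
#'
#' @param sim An `rdd_simulation` (or a list with `genome`, `genes`,
#'   `truth`, `background_pos`, `config`).
#' @param condition One of `r paste(KD_CONDITIONS, collapse = ", ")`.
#' @param individual Individual name from the config.
#' @return List with `dna` and `rna` pileup data.frames.
#' @export
simulate_pileups <- function(sim, condition = "control",
                             individual = sim$config$individuals[1]) {
  config <- sim$config
  if (!condition %in% KD_CONDITIONS)
    stop_rdd("unknown condition '%s'", condition)
  ii <- match(individual, config$individuals)
  if (is.na(ii)) stop_rdd("unknown individual '%s'", individual)
  truth <- sim$truth
  ref <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  contig <- names(sim$genome)[1]

  bg <- sim$background_pos
  pos <- c(truth$pos, bg$pos)
  true_base <- ref[pos + 1L]
  variant <- c(truth$rna_allele, rep(NA_character_, nrow(bg)))
  lv_col <- paste0("level_", condition)
  if (condition == "control") lv_col <- "level_control"
  level <- c(truth[[lv_col]], rep(0, nrow(bg)))
  owner <- c(truth$individual, rep(NA_character_, nrow(bg)))
  level[!is.na(owner) & owner != individual] <- 0
  strand <- c(truth$strand, bg$strand)
  uq <- c(rep(TRUE, nrow(truth)), bg$unique)

  set.seed(config$seed %% 100000L * 17L + cond_index(condition) * 1000L +
             ii * 100L + 7L)
  dna_counts <- draw_counts(true_base, NA_character_, rep(0, length(pos)),
                            rep(config$dna_depth, length(pos)),
                            config$error_rate)
  rna_depth <- rpois(length(pos), config$rna_depth)
  rna_counts <- draw_counts(true_base, variant, level, rna_depth,
                            config$error_rate)
  ord <- order(pos)
  mk <- function(counts, molecule, strand_col) {
    data.frame(contig = contig, pos = pos, sample = individual,
               molecule = molecule, A = counts[, "A"], C = counts[, "C"],
               G = counts[, "G"], T = counts[, "T"], strand = strand_col,
               unique = uq, stringsAsFactors = FALSE)[ord, ]
  }
  list(dna = mk(dna_counts, "DNA", rep("*", length(pos))),
       rna = mk(rna_counts, "RNA", strand))
}

#' Simulate per-transcript expression counts for one condition
#'
#' Counts are Poisson draws around `base_mean * multiplier(condition)`;
#' multipliers come from the planted up/down sets and the reciprocal
#' isoform-switch pairs (knockdown conditions only).
#'
#' @param sim An `rdd_simulation`.
#' @param condition One of `r paste(KD_CONDITIONS, collapse = ", ")`.
#' @return Data.frame `transcript_id`, `count`, `total` usable with
#'   [transcript_expression()].
#' @export
simulate_expression <- function(sim, condition = "control") {
  config <- sim$config
  te <- sim$truth_expression
  mult <- if (condition == "control") rep(1, nrow(te)) else te$kd_multiplier
  set.seed(config$seed %% 100000L * 23L + cond_index(condition) * 31L + 3L)
  count <- rpois(nrow(te), te$base_mean * mult)
  data.frame(transcript_id = te$transcript_id, count = count,
             total = sum(count), stringsAsFactors = FALSE)
}

#' Run the full synthetic-data generator
#'
#' Composes [generate_genome()], [plant_sites()], background-position
#' sampling, the expression truth, and [simulate_pileups()] /
#' [simulate_expression()] for every individual and condition.
#'
#' @param config A [simulation_config()].
#' @return List of class `rdd_simulation`: `config`, `genome`, `repeats`,
#'   `genes`, `truth` (site ledger), `truth_expression` (transcript
#'   ledger), `background_pos`, `pileups[[individual]]$dna` /
#'   `$rna[[condition]]`, and `expression[[condition]]`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  geno <- generate_genome(config)
  truth <- plant_sites(geno, config)

  set.seed(config$seed + 2L)
  spans <- transcript_spans(geno$genes)
  genic_pos <- positions_in(data.frame(start = spans$start, end = spans$end))
  genic_pos <- setdiff(genic_pos, truth$pos)
  nbg <- min(config$background_positions, length(genic_pos))
  bg_pos <- sort(genic_pos[sample.int(length(genic_pos), nbg)])
  strand_of <- site_strand(rep(config$contig, nbg), bg_pos, geno$genes)
  strand_of[strand_of %in% c("both", "none")] <- "*"
  bg <- data.frame(pos = bg_pos, strand = strand_of,
                   unique = runif(nbg) >= config$nonunique_fraction,
                   stringsAsFactors = FALSE)

  te <- spans[, c("transcript_id", "gene_id")]
  te$base_mean <- rlnorm(nrow(te), config$expr_base_meanlog,
                         config$expr_base_sdlog)
  te$class <- "none"
  te$kd_multiplier <- 1
  switch_genes <- character(0)
  if (config$n_isoform_switch > 0) {
    two_iso <- names(which(table(te$gene_id) >= 2))
    switch_genes <- sample(two_iso, min(config$n_isoform_switch,
                                        length(two_iso)))
    for (g in switch_genes) {
      idx <- which(te$gene_id == g)[1:2]
      m <- mean(te$base_mean[idx])
      te$base_mean[idx] <- m  # equal base means keep the gene total flat
      te$class[idx] <- "switch"
      te$kd_multiplier[idx] <- c(config$expr_fold, 1 / config$expr_fold)
    }
  }
  free <- which(te$class == "none")
  n_up <- min(config$expr_n_up, length(free))
  up <- sample(free, n_up)
  te$class[up] <- "up"; te$kd_multiplier[up] <- config$expr_fold
  free <- which(te$class == "none")
  n_dn <- min(config$expr_n_down, length(free))
  dn <- sample(free, n_dn)
  te$class[dn] <- "down"; te$kd_multiplier[dn] <- 1 / config$expr_fold

  sim <- structure(list(config = config, genome = geno$genome,
                        repeats = geno$repeats, genes = geno$genes,
                        truth = truth, truth_expression = te,
                        background_pos = bg),
                   class = "rdd_simulation")
  sim$pileups <- lapply(setNames(nm = config$individuals), function(ind) {
    ctrl <- simulate_pileups(sim, "control", ind)
    rna <- c(list(control = ctrl$rna),
             lapply(setNames(nm = KD_CONDITIONS[-1]), function(cd)
               simulate_pileups(sim, cd, ind)$rna))
    list(dna = ctrl$dna, rna = rna)
  })
  sim$expression <- lapply(setNames(nm = KD_CONDITIONS), function(cd)
    simulate_expression(sim, cd))
  sim
}

#' Write a simulated dataset to a directory
#'
#' Emits FASTA, GFF3, BED, per-individual/condition pileup TSVs,
#' per-condition count tables and the truth ledger TSV.
#'
#' @param sim An `rdd_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models(sim$genes, file.path(dir, "genes.gff3"))
  write_repeats(sim$repeats, file.path(dir, "repeats.bed"))
  for (ind in names(sim$pileups)) {
    write_pileup(sim$pileups[[ind]]$dna,
                 file.path(dir, sprintf("%s_dna.tsv", ind)))
    for (cd in names(sim$pileups[[ind]]$rna))
      write_pileup(sim$pileups[[ind]]$rna[[cd]],
                   file.path(dir, sprintf("%s_%s_rna.tsv", ind, cd)))
  }
  for (cd in names(sim$expression))
    write.table(sim$expression[[cd]],
                file.path(dir, sprintf("counts_%s.tsv", cd)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth_expression, file.path(dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
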