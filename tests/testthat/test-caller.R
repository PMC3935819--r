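test_that("DNA genotype calling enforces concordance and coverage", {
  p <- calling_params()
  expect_equal(call_dna_genotype(pileup_row(A = 15L), p)$allele, "A")
  r <- call_dna_genotype(pileup_row(A = 14L, G = 1L), p)
  expect_true(is.na(r$allele))
  expect_equal(r$reason, "heterozygous_or_discordant")
  expect_equal(call_dna_genotype(pileup_row(A = 9L), p)$reason,
               "low_coverage")
  expect_equal(call_dna_genotype(pileup_row(), p)$reason, "no_data")
  # relaxed concordance admits a small discordant fraction
  p95 <- calling_params(require_dna_concordance = 0.95)
  expect_equal(call_dna_genotype(pileup_row(A = 19L, G = 1L), p95)$allele, "A")
})

test_that("RDD level is the top non-DNA allele over total RNA reads", {
  r <- compute_rdd_level(pileup_row(molecule = "RNA", A = 2L, G = 8L), "A")
  expect_equal(r$variant, "G")
  expect_equal(r$level, 0.8)
  expect_false(r$tie)

  r0 <- compute_rdd_level(pileup_row(molecule = "RNA", A = 10L), "A")
  expect_true(is.na(r0$variant))
  expect_equal(r0$level, 0)
})

test_that("variant-allele ties resolve by fixed allele order and are flagged", {
  r <- compute_rdd_level(pileup_row(molecule = "RNA", A = 4L, G = 3L, T = 3L),
                         "A")
  expect_equal(r$variant, "G")
  expect_equal(r$level, 0.3)
  expect_true(r$tie)
  # oracle: enumerate every two-way tie among non-DNA alleles; the winner
  # must always be the earlier allele in A < C < G < T
  for (dna in c("A", "C", "G", "T")) {
    others <- setdiff(c("A", "C", "G", "T"), dna)
    for (i in 1:2) for (j in (i + 1):3) {
      counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
      counts[dna] <- 4L; counts[others[i]] <- 3L; counts[others[j]] <- 3L
      r <- compute_rdd_level(pileup_row(molecule = "RNA",
                                        A = counts[["A"]], C = counts[["C"]],
                                        G = counts[["G"]], T = counts[["T"]]),
                             dna)
      expect_equal(r$variant, sort(c(others[i], others[j]))[1])
      expect_true(r$tie)
    }
  }
})

test_that("12-type classification complements on the minus strand", {
  expect_equal(classify_rdd_type("A", "G", "+"), "A-to-G")
  expect_equal(classify_rdd_type("T", "C", "-"), "A-to-G")
  expect_equal(classify_rdd_type("C", "A", "+"), "C-to-A")
  expect_error(classify_rdd_type("A", "A", "+"), "identical")
  # complement symmetry over all 12 ordered pairs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (d in names(comp)) for (v in setdiff(names(comp), d)) {
    expect_equal(classify_rdd_type(d, v, "-"),
                 classify_rdd_type(comp[[d]], comp[[v]], "+"))
  }
  expect_equal(sort(unique(as.vector(vapply(names(comp), function(d)
    vapply(setdiff(names(comp), d), function(v)
      classify_rdd_type(d, v, "+"), character(1)), character(3))))),
    rdd_types())
})

test_that("call_sites composes the filter cascade with annotation", {
  genes <- tiny_gene()  # plus strand, spans 0..1000
  repeats <- data.frame(contig = "chr1", start = 80L, end = 360L,
                        name = "Alu", strand = "+", is_alu = TRUE,
                        pair_id = NA_character_, stringsAsFactors = FALSE)
  dna <- rbind(pileup_row(pos = 100L, A = 20L),
               pileup_row(pos = 200L, A = 20L),
               pileup_row(pos = 300L, A = 19L, C = 1L))
  rna <- rbind(rna_row_level(100L, "A", "G", 0.75, 20L),
               rna_row_level(200L, "A", "G", 0.05, 20L),
               rna_row_level(300L, "A", "G", 0.50, 20L))
  calls <- call_sites(dna, rna, genes, repeats)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100L)
  expect_equal(calls$rdd_type, "A-to-G")
  expect_equal(calls$level, 0.75)
  expect_true(calls$is_alu)
  expect_equal(calls$strand, "+")
  cnt <- attr(calls, "counters")
  expect_equal(cnt$rejected_genotype, 1L)  # the heterozygous position
  expect_equal(cnt$below_level, 1L)        # the 5% position
})

test_that("non-unique positions and RNA-only positions are excluded", {
  dna <- pileup_row(pos = 100L, A = 20L, unique = FALSE)
  rna <- rbind(rna_row_level(100L, "A", "G", 0.5),
               rna_row_level(400L, "A", "G", 0.5))
  calls <- call_sites(dna, rna, NULL, NULL)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "counters")$nonunique, 1L)
  expect_equal(attr(calls, "counters")$skipped_no_dna, 1L)
  # without the uniqueness requirement the site is called
  calls2 <- call_sites(dna, rna[1, ], NULL, NULL,
                       calling_params(require_unique_mapping = FALSE))
  expect_equal(nrow(calls2), 1L)
})

test_that("calls in minus-strand genes are labeled on the transcribed strand", {
  genes <- tiny_gene(strand = "-")
  dna <- pileup_row(pos = 500L, T = 20L)
  rna <- rna_row_level(500L, "T", "C", 0.5, 20L, strand = "-")
  calls <- call_sites(dna, rna, genes, NULL)
  expect_equal(calls$rdd_type, "A-to-G")
  expect_equal(calls$dna_allele, "T")  # reference strand
  expect_equal(calls$strand, "-")
  # overlapping genes on both strands -> plus-strand label, flagged
  both <- gm_rows(gm_row("G1", "G1.T1", "exon", 0, 1000, "+"),
                  gm_row("G2", "G2.T1", "exon", 0, 1000, "-"))
  calls2 <- call_sites(dna, rna, both, NULL)
  expect_true(calls2$strand_unknown)
  expect_equal(calls2$rdd_type, "T-to-C")
})

test_that("decisions agree with a brute-force oracle on random pileup pairs", {
  # independent oracle: literal transcription of the four thresholds
  oracle <- function(d, r, min_dna = 10, min_rna = 10, min_level = 0.10) {
    if (sum(d) < min_dna) return(NULL)
    if (max(d) != sum(d)) return(NULL)          # 100% DNA concordance
    dna_allele <- c("A", "C", "G", "T")[which.max(d)]
    if (sum(r) < min_rna) return(NULL)
    nd <- setdiff(c("A", "C", "G", "T"), dna_allele)
    counts <- setNames(r, c("A", "C", "G", "T"))[nd]
    best <- names(counts)[which.max(counts)]    # which.max = first max
    if (counts[[best]] == 0) return(NULL)
    level <- counts[[best]] / sum(r)
    if (level < min_level) return(NULL)
    list(allele = dna_allele, variant = best, level = level)
  }
  set.seed(11)
  params <- calling_params()
  for (i in 1:400) {
    d <- as.integer(rmultinom(1, sample(0:14, 1), runif(4)))
    r <- as.integer(rmultinom(1, sample(0:14, 1), runif(4)))
    decide <- rddscope:::decide_calls(matrix(d, 1), matrix(r, 1), params)
    want <- oracle(d, r)
    if (is.null(want)) {
      expect_false(decide$call, label = paste(d, collapse = ","))
    } else {
      expect_true(decide$call)
      expect_equal(decide$dna_allele, want$allele)
      expect_equal(decide$variant, want$variant)
      expect_equal(decide$level, want$level)
    }
  }
})

test_that("threshold changes are monotone in the call set", {
  sim <- shared_sim()
  ind <- sim$config$individuals[1]
  dna <- sim$pileups[[ind]]$dna
  rna <- sim$pileups[[ind]]$rna$control
  key <- function(calls) paste(calls$contig, calls$pos, calls$rdd_type)
  base <- call_sites(dna, rna, sim$genes, sim$repeats, calling_params())
  stricter <- call_sites(dna, rna, sim$genes, sim$repeats,
                         calling_params(min_rdd_level = 0.25))
  looser <- call_sites(dna, rna, sim$genes, sim$repeats,
                       calling_params(min_dna_coverage = 5,
                                      min_rna_coverage = 5))
  expect_true(all(key(stricter) %in% key(base)))
  expect_true(all(key(base) %in% key(looser)))
})

test_that("complementing all reads and strands leaves type labels fixed", {
  sim <- shared_sim()
  ind <- sim$config$individuals[1]
  dna <- sim$pileups[[ind]]$dna
  rna <- sim$pileups[[ind]]$rna$control
  flip <- c("+" = "-", "-" = "+", "*" = "*")
  comp_pu <- function(pu) {
    out <- pu
    out$A <- pu$T; out$T <- pu$A; out$C <- pu$G; out$G <- pu$C
    out$strand <- unname(flip[pu$strand])
    out
  }
  comp_genes <- as.data.frame(sim$genes)
  comp_genes$strand <- unname(flip[comp_genes$strand])
  comp_genes <- gene_models(comp_genes)
  a <- call_sites(dna, rna, sim$genes, sim$repeats)
  b <- call_sites(comp_pu(dna), comp_pu(rna), comp_genes, sim$repeats)
  expect_equal(b$pos, a$pos)
  expect_equal(b$rdd_type, a$rdd_type)
  expect_equal(b$level, a$level)
})

test_that("cross-individual intersection keys on position and type", {
  a <- rbind(merged_call(100), merged_call(200), merged_call(300))
  b <- rbind(merged_call(100), merged_call(300, rna_allele = "T",
                                           rdd_type = "A-to-T"))
  a$sample <- "IND1"; b$sample <- "IND2"
  a$level <- c(0.5, 0.5, 0.5); b$level <- c(0.3, 0.4)
  m <- intersect_individuals(list(IND1 = a, IND2 = b))
  # brute-force oracle: outer join on (contig, pos, type)
  expect_equal(m$pos, 100L)        # 200 absent from IND2; 300 differs in type
  expect_equal(m$level, 0.4)       # mean of 0.5 and 0.3
  expect_equal(m$ind_levels, "IND1=0.5;IND2=0.3")
  expect_error(intersect_individuals(list(IND1 = a)), "two individuals")
})

test_that("Alu partition conserves calls and type counts", {
  sim <- shared_sim()
  ind <- sim$config$individuals
  merged <- intersect_individuals(lapply(setNames(nm = ind), function(i)
    call_sites(sim$pileups[[i]]$dna, sim$pileups[[i]]$rna$control,
               sim$genes, sim$repeats)))
  part <- partition_by_repeat(merged, sim$repeats)
  expect_equal(nrow(part$alu) + nrow(part$non_alu), nrow(merged))
  expect_equal(sum(part$type_counts), nrow(merged))
  expect_equal(sum(part$type_counts[, "alu"]), nrow(part$alu))
  # planted composition: the Alu partition is overwhelmingly A-to-G
  expect_gt(part$type_counts["A-to-G", "alu"] / nrow(part$alu), 0.95)
})
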