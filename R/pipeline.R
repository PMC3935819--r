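REPORT_VERSION <- "1.0"

#' Run the full simulate - call - knockdown - features - expression pipeline
#'
#' Simulates a dataset under `config`, calls sites per individual, keeps
#' the cross-individual intersection, partitions by Alu, classifies
#' knockdown responses for ADAR1/ADAR2/double knockdown, derives the
#' knockdown FDR bound and the enzyme Venn partition, computes the site
#' features (neighbor profile, clustering, inverted-repeat proximity,
#' regions, hyperediting, ARE enrichment in edited transcripts) and the
#' expression analyses (fold changes, isoform switching,
#' editing-expression correlation), and assembles everything into one
#' machine-readable report.
#'
#' @param config A [simulation_config()].
#' @param calling A [calling_params()] (or an argument list for it).
#' @param kd_threshold,kd_mode Knockdown response threshold and mode
#'   (see [compare_conditions()]).
#' @param window Clustering window in nt (default 25).
#' @param hyper_min Hyperediting threshold (default 50, strict).
#' @param near_limit Inverted-repeat "near" bound in nt (default 1000).
#' @param fold_threshold Expression fold-change threshold (default 2).
#' @param validation_tallies Optional data.frame for [combined_fdr()]
#'   (columns `method`, `validated`, `tested`); reported when given.
#' @param out_dir Optional directory: writes `report.json` and
#'   `sites.tsv`.
#' @return A list of class `rdd_report` (the report), with the simulation
#'   and intermediate objects attached as attribute `"objects"`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         calling = calling_params(),
                         kd_threshold = 0.20, kd_mode = "relative",
                         window = 25L, hyper_min = 50L,
                         near_limit = 1000L, fold_threshold = 2.0,
                         validation_tallies = NULL, out_dir = NULL) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (!inherits(calling, "calling_params"))
    calling <- do.call(calling_params, calling)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_rdd("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- stage("simulate", simulate_dataset(config))
  inds <- config$individuals

  per_ind <- stage("call", lapply(setNames(nm = inds), function(ind)
    call_sites(sim$pileups[[ind]]$dna, sim$pileups[[ind]]$rna$control,
               sim$genes, sim$repeats, calling)))
  merged <- stage("call", intersect_individuals(per_ind, calling))
  part <- partition_by_repeat(merged)

  kd_rna <- function(cd) lapply(sim$pileups, `[[`, c("rna", cd))
  comps <- stage("knockdown", lapply(
    setNames(nm = c("ADAR1_KD", "ADAR2_KD", "double_KD")), function(cd)
      compare_conditions(merged, kd_rna(cd), condition = cd,
                         threshold = kd_threshold, mode = kd_mode,
                         min_coverage = calling$min_rna_coverage)))
  venn <- venn_partition(comps$ADAR1_KD, comps$ADAR2_KD)

  ag <- merged[merged$rdd_type == "A-to-G", , drop = FALSE]
  other <- merged[merged$rdd_type != "A-to-G", , drop = FALSE]
  feats <- stage("features", {
    prof <- if (nrow(ag)) neighbor_profile(ag, sim$genome) else NULL
    irp <- inverted_repeat_proximity(merged, sim$repeats, near_limit)
    hyper <- detect_hyperedited(merged, sim$genes, hyper_min)
    regions <- assign_region(merged, sim$genes)
    list(profile = prof, irp = irp, hyper = hyper, regions = regions)
  })

  # ARE enrichment: transcripts carrying A-to-G calls vs the others
  are <- stage("features", {
    sp <- transcript_spans(sim$genes)
    hit <- GenomicRanges::countOverlaps(
      gr0(sp$contig, sp$start, sp$end), gr_pos(ag$contig, ag$pos)) > 0
    seq_of <- function(rows) Biostrings::DNAStringSet(substring(
      as.character(sim$genome[[1]]), rows$start + 1L, rows$end))
    if (any(hit) && any(!hit))
      motif_enrichment(seq_of(sp[hit, ]), seq_of(sp[!hit, ]),
                       are_patterns()$HuR_TAWTTTT)
    else NULL
  })

  expr <- stage("expression", {
    ctrl <- transcript_expression(sim$expression$control, sim$genes)
    kd <- transcript_expression(sim$expression$ADAR1_KD, sim$genes)
    changes <- classify_changes(ctrl, kd, sim$genes, fold_threshold)
    sw <- detect_isoform_switching(changes)
    corr <- tryCatch(
      editing_expression_correlation(comps$ADAR1_KD, changes, sim$genes),
      error = function(e) list(r = NA_real_, p_value = NA_real_,
                               n_genes = 0L))
    list(changes = changes, switching = sw, correlation = corr)
  })

  sum_of <- function(cmp) list(
    a_to_g = response_summary(cmp, "A-to-G"),
    other = response_summary(cmp, "other"))
  region_tab <- function(rows, lab)
    as.list(table(factor(lab, levels = REGION_LABELS)))
  dir_n <- function(df) as.list(table(factor(
    df$direction, levels = c("increased", "decreased", "unchanged"))))

  report <- list(
    version = REPORT_VERSION,
    seed = config$seed,
    individuals = inds,
    calls = list(
      per_individual = lapply(per_ind, nrow),
      merged = nrow(merged),
      a_to_g = nrow(ag),
      type_counts = as.list(table(factor(merged$rdd_type,
                                         levels = rdd_types()))),
      alu = nrow(part$alu), non_alu = nrow(part$non_alu),
      alu_percent_a_to_g = if (nrow(part$alu))
        proportion(sum(part$alu$rdd_type == "A-to-G"),
                   nrow(part$alu))$percent else NA,
      non_alu_percent_a_to_g = if (nrow(part$non_alu))
        proportion(sum(part$non_alu$rdd_type == "A-to-G"),
                   nrow(part$non_alu))$percent else NA),
    knockdown = list(
      ADAR1_KD = sum_of(comps$ADAR1_KD),
      ADAR2_KD = sum_of(comps$ADAR2_KD),
      double_KD = sum_of(comps$double_KD),
      fdr_bound_adar1 = tryCatch(kd_fdr_bound(comps$ADAR1_KD),
                                 error = function(e) NA_real_),
      venn = venn[c("adar1_only", "adar2_only", "shared",
                    "total_responsive")]),
    features = list(
      cluster_fraction_a_to_g = cluster_fraction(ag, window),
      cluster_fraction_other = cluster_fraction(other, window),
      inverted_repeat_fractions = as.list(feats$irp$fractions),
      regions_a_to_g = region_tab(ag, feats$regions[merged$rdd_type == "A-to-G"]),
      regions_other = region_tab(other, feats$regions[merged$rdd_type != "A-to-G"]),
      hyperedited_transcripts = nrow(feats$hyper$transcripts),
      hyperedited_fraction = feats$hyper$fraction,
      neighbor_g_minus1 = if (!is.null(feats$profile))
        feats$profile$freq["G", "-1"] else NA,
      neighbor_g_plus1 = if (!is.null(feats$profile))
        feats$profile$freq["G", "1"] else NA,
      are_enrichment = if (!is.null(are))
        list(table = as.list(as.vector(are$table)),
             chisq_p = are$p_value, odds_ratio = are$odds_ratio)
      else NULL),
    expression = list(
      transcripts = dir_n(expr$changes$transcripts),
      genes = dir_n(expr$changes$genes),
      isoform_switch_genes = nrow(expr$switching),
      editing_expression_r = expr$correlation$r),
    validation_fdr = if (!is.null(validation_tallies))
      combined_fdr(validation_tallies) else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    write_site_table(merged, file.path(out_dir, "sites.tsv"))
  }
  structure(report, class = "rdd_report",
            objects = list(sim = sim, per_individual = per_ind,
                           merged = merged, comparisons = comps,
                           venn = venn, features = feats,
                           expression = expr))
}
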