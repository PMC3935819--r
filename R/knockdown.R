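#' Measure RDD levels of known sites in an RNA pileup
#'
#' Recomputes, without any calling thresholds, the variant-allele fraction
#' of each given site in one sample's RNA pileup. This is how knockdown
#' samples are evaluated: a site whose editing was abolished would never
#' pass the >= 10% calling filter again, but its level (zero) is still a
#' measurement.
#'
#' @param sites Call data.frame (needs `contig`, `pos`, `rna_allele` on the
#'   reference strand).
#' @param rna RNA pileup data.frame for one sample.
#' @param min_coverage Minimum RNA reads for the measurement to count as
#'   evaluable (default 10).
#' @return Data.frame aligned with `sites`: `level`, `rna_cov`,
#'   `evaluable`. Sites absent from the pileup get coverage 0.
#' @export
measure_site_levels <- function(sites, rna, min_coverage = 10L) {
  idx <- match(paste(sites$contig, sites$pos), paste(rna$contig, rna$pos))
  cov <- level <- numeric(nrow(sites))
  hit <- !is.na(idx)
  if (any(hit)) {
    m <- count_matrix(rna[idx[hit], , drop = FALSE])
    tot <- rowSums(m)
    vc <- m[cbind(seq_len(nrow(m)), match(sites$rna_allele[hit], ALLELES))]
    cov[hit] <- tot
    level[hit] <- ifelse(tot > 0, vc / tot, 0)
  }
  data.frame(level = level, rna_cov = cov,
             evaluable = cov >= min_coverage, stringsAsFactors = FALSE)
}

#' Compare per-site editing levels between control and knockdown
#'
#' For every site of the control call set, measures the knockdown level in
#' each individual and classifies the response. A site is `decreased_ge20`
#' when its level dropped by at least `threshold` (relative change
#' `(control - kd)/control >= threshold` by default, or absolute difference
#' with `mode = "absolute"`) in *every* individual; `increased_ge20`
#' symmetrically; `unchanged` otherwise. `abolished` flags sites whose
#' knockdown level is exactly zero in every individual (a subset of
#' `decreased_ge20`). Sites without sufficient knockdown coverage in every
#' individual are `not_evaluable` and excluded from category counts.
#'
#' @param control_calls Merged control calls from [intersect_individuals()]
#'   (carrying per-individual levels in `ind_levels`).
#' @param kd_rna Named list, individual -> RNA pileup data.frame of the
#'   knockdown condition. Names must match the control individuals.
#' @param condition Label, e.g. `"ADAR1_KD"`.
#' @param threshold Response threshold (default 0.20).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param min_coverage Minimum knockdown RNA coverage per individual.
#' @return Data.frame with one row per control site: site key columns,
#'   `level_control` and `level_kd` (across-individual means),
#'   `relative_change`, `category`, `abolished`, `condition`.
#' @export
compare_conditions <- function(control_calls, kd_rna,
                               condition = "ADAR1_KD",
                               threshold = 0.20,
                               mode = c("relative", "absolute"),
                               min_coverage = 10L) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stop_rdd("threshold must be in (0,1]")
  ctrl_lv <- parse_ind_levels(control_calls$ind_levels)
  inds <- names(ctrl_lv[[1]])
  if (!all(inds %in% names(kd_rna)))
    stop_rdd("kd_rna must be a named list covering individuals: %s",
             paste(inds, collapse = ", "))
  n <- nrow(control_calls)
  kd_lv <- kd_ok <- matrix(0, n, length(inds), dimnames = list(NULL, inds))
  for (ind in inds) {
    m <- measure_site_levels(control_calls, kd_rna[[ind]], min_coverage)
    kd_lv[, ind] <- m$level
    kd_ok[, ind] <- m$evaluable
  }
  cl <- do.call(rbind, lapply(ctrl_lv, function(x) x[inds]))
  evaluable <- rowSums(kd_ok) == length(inds)
  delta <- if (mode == "relative") (cl - kd_lv) / cl else cl - kd_lv
  dec <- rowSums(delta >= threshold) == length(inds)
  inc <- rowSums(delta <= -threshold) == length(inds)
  abol <- rowSums(kd_lv == 0) == length(inds) & rowSums(cl > 0) == length(inds)
  category <- rep("unchanged", n)
  category[dec] <- "decreased_ge20"
  category[inc] <- "increased_ge20"
  category[!evaluable] <- "not_evaluable"
  data.frame(
    contig = control_calls$contig, pos = control_calls$pos,
    rdd_type = control_calls$rdd_type,
    dna_allele = control_calls$dna_allele,
    rna_allele = control_calls$rna_allele,
    strand = control_calls$strand, is_alu = control_calls$is_alu,
    level_control = rowMeans(cl), level_kd = rowMeans(kd_lv),
    relative_change = (rowMeans(cl) - rowMeans(kd_lv)) / rowMeans(cl),
    category = category, abolished = abol & evaluable,
    condition = condition, stringsAsFactors = FALSE)
}

#' Summarize knockdown responses by category
#'
#' @param comparisons Output of [compare_conditions()].
#' @param type_filter `"A-to-G"` (default), `"other"` (the 11 non-A-to-G
#'   types) or `"all"`.
#' @return A list: `evaluable`, per-category `counts`, `abolished`,
#'   `percent_decreased` (decreased/evaluable, rounded half away from zero
#'   to the nearest integer).
#' @export
response_summary <- function(comparisons, type_filter = "A-to-G") {
  sub <- switch(type_filter,
    "all" = comparisons,
    "other" = comparisons[comparisons$rdd_type != "A-to-G", , drop = FALSE],
    comparisons[comparisons$rdd_type == type_filter, , drop = FALSE])
  ev <- sub[sub$category != "not_evaluable", , drop = FALSE]
  counts <- c(table(factor(ev$category,
    levels = c("decreased_ge20", "increased_ge20", "unchanged"))))
  list(type_filter = type_filter,
       evaluable = nrow(ev),
       counts = counts,
       abolished = sum(ev$abolished),
       percent_decreased = if (nrow(ev) > 0)
         round_half_up(100 * counts[["decreased_ge20"]] / nrow(ev)) else NA_real_)
}

site_key <- function(x) paste(x$contig, x$pos, x$rdd_type)

#' Partition responsive sites between two knockdown conditions
#'
#' Sites whose level decreased by the threshold in both conditions are
#' shared targets; sites responding in exactly one condition are exclusive
#' to that enzyme.
#'
#' @param resp_adar1,resp_adar2 Outputs of [compare_conditions()] for the
#'   two conditions.
#' @return A list of class `venn_partition`: `adar1_only`, `adar2_only`,
#'   `shared`, `total_responsive` (= sum of the three), plus the site keys
#'   of each compartment.
#' @export
venn_partition <- function(resp_adar1, resp_adar2) {
  d1 <- site_key(resp_adar1[resp_adar1$category == "decreased_ge20", ])
  d2 <- site_key(resp_adar2[resp_adar2$category == "decreased_ge20", ])
  shared <- intersect(d1, d2)
  only1 <- setdiff(d1, d2)
  only2 <- setdiff(d2, d1)
  structure(list(adar1_only = length(only1), adar2_only = length(only2),
                 shared = length(shared),
                 total_responsive = length(only1) + length(only2) + length(shared),
                 keys = list(adar1_only = only1, adar2_only = only2,
                             shared = shared)),
            class = "venn_partition")
}

#' Knockdown-based FDR bound for A-to-G calls
#'
#' The fraction of evaluable A-to-G sites that did *not* respond to the
#' knockdown (level decrease below the threshold): since true
#' enzyme-mediated editing should respond, this fraction bounds the false
#' discovery rate of the call set from above.
#'
#' @param comparisons Output of [compare_conditions()]; restricted
#'   internally to A-to-G sites.
#' @return Fraction in `[0, 1]`.
#' @export
kd_fdr_bound <- function(comparisons) {
  ag <- comparisons[comparisons$rdd_type == "A-to-G" &
                      comparisons$category != "not_evaluable", , drop = FALSE]
  if (nrow(ag) == 0) stop_rdd("kd_fdr_bound: no evaluable A-to-G sites")
  dec <- sum(ag$category == "decreased_ge20")
  (nrow(ag) - dec) / nrow(ag)
}
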