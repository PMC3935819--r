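#' Pooled validation-based FDR
#'
#' Validation tallies from orthogonal assays (e.g. Sanger re-sequencing,
#' droplet digital PCR) are pooled by total counts: the FDR estimate is
#' the summed number of failed sites over the summed number tested, not
#' the average of per-method rates. With 24/25 Sanger and 5/6 ddPCR this
#' gives 2/31, about 6.5%.
#'
#' @param tallies Data.frame with columns `method`, `validated`, `tested`
#'   (or a list of such rows).
#' @return Fraction in `[0, 1]`.
#' @export
combined_fdr <- function(tallies) {
  tallies <- as.data.frame(tallies)
  if (!all(c("validated", "tested") %in% names(tallies)))
    stop_rdd("combined_fdr: need columns 'validated' and 'tested'")
  if (any(tallies$validated < 0 | tallies$validated > tallies$tested))
    stop_rdd("combined_fdr: require 0 <= validated <= tested")
  tot <- sum(tallies$tested)
  if (tot == 0) stop_rdd("combined_fdr: zero sites tested")
  sum(tallies$tested - tallies$validated) / tot
}

#' Build a validation tally table
#' @param ... Named `c(validated, tested)` pairs, e.g.
#'   `sanger = c(24, 25), ddpcr = c(5, 6)`.
#' @return Data.frame with columns `method`, `validated`, `tested`.
#' @export
validation_tally <- function(...) {
  x <- list(...)
  data.frame(method = names(x),
             validated = vapply(x, `[`, numeric(1), 1),
             tested = vapply(x, `[`, numeric(1), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment test on a 2x2 overlap table
#'
#' Rows are target/control, columns positive/negative. Reports row
#' proportions (with rounded percentages), the 1-df chi-square test
#' (without continuity correction), Fisher's exact test, and the odds
#' ratio (Haldane 0.5 correction applied when any cell is zero).
#'
#' @param table 2x2 numeric matrix.
#' @return List: `table`, `proportions`, `percents`, `chisq_stat`,
#'   `p_value`, `fisher_p`, `odds_ratio`.
#' @export
overlap_enrichment <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
    stop_rdd("overlap_enrichment: need a non-negative 2x2 table")
  if (any(rowSums(tab) == 0))
    stop_rdd("overlap_enrichment: zero row margin")
  prop <- tab[, 1] / rowSums(tab)
  if (any(colSums(tab) == 0)) {
    warning("degenerate table (empty column); p set to 1")
    chi <- list(statistic = c("X-squared" = 0), p.value = 1)
    fis <- list(p.value = 1)
  } else {
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    fis <- fisher.test(tab)
  }
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab,
       proportions = prop,
       percents = round_half_up(100 * prop),
       chisq_stat = unname(chi$statistic),
       p_value = chi$p.value,
       fisher_p = fis$p.value,
       odds_ratio = or)
}

#' Rounded percentage with exact fraction
#'
#' Percentages are rounded half away from zero to the nearest integer,
#' matching how ratios like 6258/6524 are conventionally printed as 96%.
#'
#' @param numerator,denominator Non-negative numbers, `denominator > 0`.
#' @return List with `percent` (integer) and `fraction` (exact).
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_rdd("proportion: denominator must be > 0")
  frac <- numerator / denominator
  list(percent = round_half_up(100 * frac), fraction = frac)
}
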