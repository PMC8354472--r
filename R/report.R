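## Descriptive statistics: grouped proportions with chi-squared contrasts,
## expression-decile binning, and IES density in well-covered MAC-destined
## sequence.

#' Grouped proportion table with a chi-squared contrast
#'
#' Cross-tabulates a grouping variable against a binary outcome and tests
#' homogeneity of proportions with a chi-squared test without continuity
#' correction.  Records with a missing outcome are excluded.  When any
#' expected cell count is below 5 the test is still reported, with a
#' small-sample warning attached.
#'
#' @param df data.frame
#' @param group name of the grouping column
#' @param outcome name of a logical column
#' @return list: `table` (group, n, k, proportion), `chisq`, `df`,
#'   `p_value`, `small_sample`
#' @export
proportions_report <- function(df, group, outcome) {
  use <- !is.na(df[[outcome]]) & !is.na(df[[group]])
  g <- factor(df[[group]][use])
  y <- as.logical(df[[outcome]][use])
  tab <- table(g, factor(y, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || nlevels(g) < 2) {
    stop("need at least two non-empty groups")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5)
  test <- suppressWarnings(chisq.test(tab, correct = FALSE))
  res <- data.frame(group = rownames(tab),
                    n = as.integer(rowSums(tab)),
                    k = as.integer(tab[, "TRUE"]),
                    proportion = tab[, "TRUE"] / rowSums(tab))
  rownames(res) <- NULL
  list(table = res, chisq = unname(test$statistic),
       df = unname(test$parameter), p_value = unname(test$p.value),
       small_sample = small)
}

#' Equal-size expression bins
#'
#' Splits genes into `n` bins of (as nearly as possible) equal size by
#' increasing expression, as used for density-vs-expression profiles.
#' Non-expressed genes (value 0) should be excluded by the caller.
#'
#' @param expression numeric vector
#' @param n number of bins (default 10)
#' @return integer bin index 1..n (1 = lowest expression)
#' @export
expression_deciles <- function(expression, n = 10L) {
  r <- rank(expression, ties.method = "first")
  as.integer(ceiling(r * n / length(expression)))
}

#' Per-species IES density in well-covered MAC-destined sequence
#'
#' Density = retained IES count / kb of MAC-destined sequence whose MIC
#' read depth reaches `min_depth`.
#'
#' @param catalog IES catalog (column `species`)
#' @param depth_track data.frame: scaffold, start, end (0-based
#'   half-open), depth; the per-window MIC read depth on the MAC
#' @param scaffold_species named species per scaffold
#' @param min_depth minimum depth (default 15)
#' @return data.frame: species, n_ies, kb, density (NA when no
#'   qualifying sequence)
#' @export
density_report <- function(catalog, depth_track, scaffold_species,
                           min_depth = 15) {
  depth_track$species <- scaffold_species[depth_track$scaffold]
  out <- lapply(unique(catalog$species), function(sp) {
    ok <- depth_track$species == sp & depth_track$depth >= min_depth
    kb <- sum(depth_track$end[ok] - depth_track$start[ok]) / 1000
    n <- sum(catalog$species == sp)
    data.frame(species = sp, n_ies = n, kb = kb,
               density = if (kb > 0) n / kb else NA_real_)
  })
  do.call(rbind, out)
}
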