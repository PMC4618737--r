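#' Configuration of the major-feature screen
#'
#' Before any statistics, features are screened for being "major": present
#' in at least half of the samples or reaching at least 1 % relative
#' abundance.  Under the default `AND_removal` rule a feature is removed
#' only if it is BOTH low-prevalence and low-abundance, so
#' abundant-but-rare and ubiquitous-but-scarce features are retained;
#' `OR_removal` removes a feature failing either criterion.
#'
#' @param min_prevalence_fraction fraction of samples a feature must be
#'   detected in (value > 0) to count as prevalent; default 0.5.
#' @param min_max_abundance abundance (as a fraction) the feature's
#'   summary abundance must reach to count as abundant; default 0.01 (1 %).
#' @param combine_rule `"AND_removal"` (default) or `"OR_removal"`.
#' @param abundance_stat per-feature summary compared against
#'   `min_max_abundance`: `"max"` across samples (default, most
#'   permissive) or `"mean"`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_prevalence_fraction = 0.5,
                          min_max_abundance = 0.01,
                          combine_rule = c("AND_removal", "OR_removal"),
                          abundance_stat = c("max", "mean")) {
  combine_rule <- match.arg(combine_rule)
  abundance_stat <- match.arg(abundance_stat)
  if (min_prevalence_fraction < 0 || min_prevalence_fraction > 1)
    stop("`min_prevalence_fraction` must lie in [0, 1]")
  if (min_max_abundance < 0 || min_max_abundance > 1)
    stop("`min_max_abundance` must lie in [0, 1]")
  structure(list(min_prevalence_fraction = min_prevalence_fraction,
                 min_max_abundance = min_max_abundance,
                 combine_rule = combine_rule,
                 abundance_stat = abundance_stat),
            class = "filter_config")
}

#' Select major features by prevalence and abundance
#'
#' @param table an [abundance_table()] with unit `"fraction"`.
#' @param cfg a [filter_config()].
#' @return The table restricted to retained features, original order
#'   preserved.  Errors if every feature would be removed.
#' @examples
#' m <- matrix(c(0.5, 0.001, 0, 0.5, 0.001, 0.004), nrow = 3,
#'             dimnames = list(c("GH13", "CE1", "GH57"), c("S1", "S2")))
#' filter_major_features(abundance_table(m), filter_config())
#' @export
filter_major_features <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "abund_table"), inherits(cfg, "filter_config"))
  if (table$unit != "fraction")
    stop("filtering expects abundances as fractions")
  v <- table$values
  if (nrow(v) == 0L) stop("table has no features")
  prevalence <- rowMeans(v > 0)
  ab <- switch(cfg$abundance_stat,
               max = apply(v, 1L, max),
               mean = rowMeans(v))
  low_prev <- prevalence < cfg$min_prevalence_fraction
  low_ab <- ab < cfg$min_max_abundance
  removed <- switch(cfg$combine_rule,
                    AND_removal = low_prev & low_ab,
                    OR_removal = low_prev | low_ab)
  if (all(removed))
    stop("all features removed; relax `min_prevalence_fraction` or ",
         "`min_max_abundance`")
  keep <- which(!removed)
  abundance_table(v[keep, , drop = FALSE],
                  feature_kinds = table$feature_kinds[keep],
                  unit = table$unit)
}
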