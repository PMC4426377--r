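# Per-individual, per-site sequencing depth related to genotype mismatches
# and to the magnitude of frequency errors.

#' Compare depth between matched and mismatched genotypes
#'
#' Joins per-base depth records to genotype comparison results on
#' `sample_id` + `site` and tests whether matched genotypes have higher
#' coverage (one-tailed rank-sum, matched > mismatched).
#'
#' @param coverage tibble with columns `sample_id`, `site` (CDS position)
#'   and `depth`.
#' @param results output of [compare_genotypes()].
#' @return List with `matched`, `mismatched` (depth vectors), their means,
#'   and `p` (one-tailed rank-sum; `NA` when either group is empty).
#' @export
coverage_by_match_status <- function(coverage, results) {
  keys <- c("sample_id", "site")
  j <- dplyr::inner_join(results[, c(keys, "match")], coverage[, c(keys, "depth")],
                         by = keys)
  if (nrow(j) == 0L) {
    stop("no overlap between coverage and comparison records", call. = FALSE)
  }
  matched <- j$depth[j$match]
  mismatched <- j$depth[!j$match]
  p <- if (length(matched) && length(mismatched)) {
    mannwhitney_one_tailed(matched, mismatched)
  } else NA_real_
  list(matched = matched, mismatched = mismatched,
       mean_matched = mean(matched), mean_mismatched = mean(mismatched),
       p = p)
}

#' Correlation between mean site coverage and |FE|
#'
#' @param mean_coverage numeric vector of per-site mean depths.
#' @param abs_fe numeric vector of per-site `|FE|`, same order.
#' @return List with `r` and `p` from [pearson_with_p()].
#' @export
coverage_vs_fe <- function(mean_coverage, abs_fe) {
  pearson_with_p(mean_coverage, abs_fe)
}
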