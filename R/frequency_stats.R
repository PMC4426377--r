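# Reference-allele frequency estimation in both datasets, frequency error
# (FE) and per-gene MAE, site classification and cross-population flagging,
# the exact binomial direction test, heterozygosity and Pearson correlations.

#' Reference-allele frequency at one site
#'
#' Counts REF alleles over all non-missing diploid genotypes. A residually
#' ambiguous gold base set containing REF contributes fractionally (1/set
#' size, i.e. 0.5 for a two-base set), avoiding a directional bias from
#' unresolved typing ambiguity.
#'
#' @param a1,a2 character vectors (one element per individual) of base-set
#'   strings (gold) or single bases (NGS); `NA` = missing.
#' @param ref_base the REF base.
#' @return Frequency of REF in `[0, 1]`.
#' @export
ref_allele_frequency <- function(a1, a2, ref_base) {
  keep <- !is.na(a1) & !is.na(a2)
  if (!any(keep)) stop("no non-missing genotypes at site", call. = FALSE)
  cnt <- function(x) {
    plain <- !grepl("/", x, fixed = TRUE)
    out <- numeric(length(x))
    out[plain] <- as.numeric(x[plain] == ref_base)
    for (i in which(!plain)) {
      b <- base_set_members(x[i])
      out[i] <- (ref_base %in% b) / length(b)
    }
    out
  }
  sum(cnt(a1[keep]) + cnt(a2[keep])) / (2 * sum(keep))
}

#' Frequency error at a site
#'
#' `FE = f_ngs - f_gold`, the difference between the REF-allele frequency in
#' the NGS call set and in the (ambiguity-corrected) gold standard.
#'
#' @param f_ngs,f_gold REF-allele frequencies in `[0, 1]`.
#' @return FE in `[-1, 1]`.
#' @export
frequency_error <- function(f_ngs, f_gold) {
  stopifnot(all(f_ngs >= 0 & f_ngs <= 1), all(f_gold >= 0 & f_gold <= 1))
  f_ngs - f_gold
}

#' Mean absolute frequency error
#'
#' @param fe_list numeric vector of per-site FE values (one gene, typically).
#' @return `mean(|FE|)`.
#' @export
mae <- function(fe_list) {
  if (length(fe_list) == 0L) stop("empty FE list", call. = FALSE)
  mean(abs(fe_list))
}

#' Classify a site by its frequency error
#'
#' `overestimated` if FE > 0.1, `underestimated` if FE < -0.1,
#' `well_estimated` if |FE| < 0.01, otherwise `intermediate`.
#'
#' @param fe numeric vector of FE values.
#' @param fe_large,fe_well class thresholds.
#' @return Character vector of class labels.
#' @export
classify_site <- function(fe, fe_large = 0.1, fe_well = 0.01) {
  stopifnot(fe_well < fe_large)
  dplyr::case_when(
    fe > fe_large ~ "overestimated",
    fe < -fe_large ~ "underestimated",
    abs(fe) < fe_well ~ "well_estimated",
    TRUE ~ "intermediate"
  )
}

#' Flag unreliable sites across populations
#'
#' A site is flagged when `|FE| > threshold` in at least `min_pops`
#' populations.
#'
#' @param fe_table tibble with columns `site`, `population`, `fe` (per-
#'   population FE; the pooled/"global" population should not be included),
#'   and optionally `locus`.
#' @param threshold absolute-FE threshold (default 0.1).
#' @param min_pops minimum number of populations (default 2).
#' @return Tibble of flagged sites with `n_pops_large` (and `locus` if
#'   present).
#' @export
unreliable_sites <- function(fe_table, threshold = 0.1, min_pops = 2) {
  keys <- intersect(c("locus", "site"), names(fe_table))
  tab <- dplyr::summarise(
    dplyr::group_by(fe_table, dplyr::across(dplyr::all_of(keys))),
    n_pops_large = sum(abs(fe) > threshold), .groups = "drop")
  tab[tab$n_pops_large >= min_pops, , drop = FALSE]
}

#' Exact binomial test for the direction of frequency deviations
#'
#' Two-sided exact binomial test of equal numbers of REF-skewed and
#' ALT-skewed sites (null probability 0.5); the p-value sums the
#' probabilities of all outcomes no more likely than the observed count.
#'
#' @param n_ref_skewed,n_alt_skewed non-negative counts of flagged sites with
#'   REF-overestimating and ALT-overestimating deviations.
#' @return Two-sided p-value.
#' @export
direction_test <- function(n_ref_skewed, n_alt_skewed) {
  stopifnot(n_ref_skewed >= 0, n_alt_skewed >= 0)
  n <- n_ref_skewed + n_alt_skewed
  if (n < 1) stop("need at least one skewed site", call. = FALSE)
  stats::binom.test(n_ref_skewed, n, p = 0.5)$p.value
}

#' Heterozygosity of a biallelic site
#'
#' @param p allele frequency in `[0, 1]`.
#' @return `H = 2 p (1 - p)`.
#' @export
heterozygosity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  2 * p * (1 - p)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return List with `r` and `p` (t-distribution, n - 2 df).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Pearson correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Heterozygosity distributions for excluded vs retained sites
#'
#' Heterozygosity is computed from the gold-standard frequencies only, so
#' differences between the excluded (flagged) and retained sets reflect true
#' diversity at the flagged sites, not NGS error.
#'
#' @param gold_freqs tibble with columns `site`, `f_gold` (pooled gold REF
#'   frequency) and optionally `locus`.
#' @param flagged tibble of flagged sites (see [unreliable_sites()]), matched
#'   on the shared key columns.
#' @return List with `excluded` and `retained` (numeric H vectors) and their
#'   means (`NaN` when a set is empty).
#' @export
heterozygosity_filter_report <- function(gold_freqs, flagged) {
  keys <- intersect(intersect(c("locus", "site"), names(gold_freqs)),
                    names(flagged))
  key_of <- function(d) do.call(paste, c(d[keys], sep = "\r"))
  is_flagged <- key_of(gold_freqs) %in% key_of(flagged)
  h <- heterozygosity(gold_freqs$f_gold)
  list(excluded = h[is_flagged], retained = h[!is_flagged],
       mean_excluded = mean(h[is_flagged]), mean_retained = mean(h[!is_flagged]))
}

#' Per-site, per-population REF-frequency table with FE
#'
#' Builds the frequency comparison table from a compared genotype table:
#' for each site and each population (plus the pooled `"global"` set), the
#' REF frequency in the corrected gold data and in the NGS calls, and their
#' difference FE. Only individuals with non-missing NGS genotypes enter
#' either denominator.
#'
#' @param results output of [compare_genotypes()]; must carry `population`
#'   and `ref` (REF base per site) columns.
#' @return Tibble: `locus` (if present), `site`, `population`, `ref_base`,
#'   `n`, `f_ngs`, `f_gold`, `fe`.
#' @export
frequency_table <- function(results) {
  stopifnot(all(c("population", "ref") %in% names(results)))
  glob <- results
  glob$population <- "global"
  both <- dplyr::bind_rows(results, glob)
  keys <- intersect(c("locus", "site", "population"), names(both))
  dplyr::summarise(
    dplyr::group_by(both, dplyr::across(dplyr::all_of(keys))),
    ref_base = ref[1],
    n = dplyr::n(),
    f_ngs = ref_allele_frequency(ngs1, ngs2, ref[1]),
    f_gold = ref_allele_frequency(gold1, gold2, ref[1]),
    fe = f_ngs - f_gold,
    .groups = "drop")
}
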