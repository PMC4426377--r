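# Per-site genotype comparison between gold-standard (Sanger-derived, possibly
# ambiguous) and NGS genotypes: the ambiguity-correction rule, the match rule,
# and mismatch summaries.

#' Correct residual gold-call ambiguity against the NGS genotype
#'
#' A gold base set with more than one base (typing ambiguity, e.g. `"A/T"`)
#' whose intersection with the NGS allele pair is non-empty is resolved to an
#' NGS base from that intersection; when both copies are ambiguous the
#' assignment maximising the subsequent match is chosen. Singleton sets and
#' ambiguous sets disjoint from the NGS pair are left unchanged.
#'
#' @param gold character vector of two base-set strings (the two gold copies).
#' @param ngs character vector of two single bases (the NGS genotype).
#' @return List with `gold` (corrected pair, copy order preserved) and
#'   `corrected` (logical: was anything altered).
#' @export
correct_ambiguity <- function(gold, ngs) {
  stopifnot(length(gold) == 2L, length(ngs) == 2L)
  opts <- lapply(gold, function(g) {
    gb <- base_set_members(g)
    if (length(gb) == 1L) return(g)
    inter <- intersect(gb, ngs)
    if (length(inter) == 0L) return(g)
    sort(inter)
  })
  if (all(lengths(opts) == 1L) && identical(unlist(opts), gold)) {
    return(list(gold = gold, corrected = FALSE))
  }
  grid <- expand.grid(a = opts[[1]], b = opts[[2]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  score <- mapply(function(a, b) genotypes_match(c(a, b), ngs),
                  grid$a, grid$b)
  pick <- grid[which.max(score), ]  # ties: first in sorted base order
  res <- c(pick$a, pick$b)
  list(gold = res, corrected = !identical(res, gold))
}

#' Do a corrected gold genotype and an NGS genotype match?
#'
#' Match requires both NGS alleles to be present in the gold genotype via a
#' one-to-one pairing of copies: each NGS base must belong to the base set of
#' its paired gold copy. A homozygous NGS call therefore needs its base in
#' both gold sets.
#'
#' @param gold character vector of two base-set strings (correction applied).
#' @param ngs character vector of two single bases.
#' @return Logical.
#' @export
genotypes_match <- function(gold, ngs) {
  g1 <- base_set_members(gold[1]); g2 <- base_set_members(gold[2])
  (ngs[1] %in% g1 && ngs[2] %in% g2) || (ngs[1] %in% g2 && ngs[2] %in% g1)
}

#' Compare gold and NGS genotype tables site by site
#'
#' Applies [correct_ambiguity()] then [genotypes_match()] per row. Rows with a
#' missing NGS genotype (`NA`) are dropped.
#'
#' @param genotypes tibble with columns `sample_id`, `site`, `gold1`, `gold2`
#'   (base-set strings), `ngs1`, `ngs2` (single bases or `NA`), and optionally
#'   `locus`, `population`.
#' @return The input rows (non-missing NGS only) with `gold1`, `gold2`
#'   replaced by corrected values and new columns `corrected` and `match`.
#' @export
compare_genotypes <- function(genotypes) {
  gt <- genotypes[!is.na(genotypes$ngs1) & !is.na(genotypes$ngs2), ,
                  drop = FALSE]
  n <- nrow(gt)
  if (n == 0L) stop("no non-missing genotype comparisons", call. = FALSE)
  corrected <- logical(n)
  match <- logical(n)
  g1 <- gt$gold1; g2 <- gt$gold2; n1 <- gt$ngs1; n2 <- gt$ngs2
  plain <- !grepl("/", g1, fixed = TRUE) & !grepl("/", g2, fixed = TRUE)
  # unambiguous fast path
  match[plain] <- (g1[plain] == n1[plain] & g2[plain] == n2[plain]) |
    (g1[plain] == n2[plain] & g2[plain] == n1[plain])
  for (i in which(!plain)) {
    cr <- correct_ambiguity(c(g1[i], g2[i]), c(n1[i], n2[i]))
    g1[i] <- cr$gold[1]; g2[i] <- cr$gold[2]
    corrected[i] <- cr$corrected
    match[i] <- genotypes_match(cr$gold, c(n1[i], n2[i]))
  }
  gt$gold1 <- g1; gt$gold2 <- g2
  gt$corrected <- corrected
  gt$match <- match
  gt
}

#' Summarise mismatches overall, per site and per individual
#'
#' @param results output of [compare_genotypes()].
#' @return List with `overall` (mismatch proportion), `n_comparisons`,
#'   `per_site` (tibble: site, n, n_mismatch, mismatch_rate; by locus if
#'   present) and `per_individual`.
#' @export
mismatch_summary <- function(results) {
  if (nrow(results) == 0L) stop("empty comparison results", call. = FALSE)
  results$mismatch <- !results$match
  site_keys <- intersect(c("locus", "site"), names(results))
  per_site <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(site_keys))),
    n = dplyr::n(), n_mismatch = sum(mismatch),
    mismatch_rate = mean(mismatch), .groups = "drop")
  per_ind <- dplyr::summarise(
    dplyr::group_by(results, sample_id),
    n = dplyr::n(), n_mismatch = sum(mismatch),
    mismatch_rate = mean(mismatch), .groups = "drop")
  list(overall = mean(results$mismatch),
       n_comparisons = nrow(results),
       per_site = per_site,
       per_individual = per_ind)
}

#' Fraction of sites concentrating a given share of mismatches
#'
#' Sites are taken in descending mismatch-count order until their cumulative
#' count reaches at least `mass_fraction` of the total; the returned value is
#' that minimal number of sites divided by the number of sites.
#'
#' @param per_site_counts non-negative integer vector of per-site mismatch
#'   counts.
#' @param mass_fraction fraction of total mismatch mass to cover, in (0, 1].
#' @return Numeric scalar in (0, 1].
#' @export
mismatch_concentration <- function(per_site_counts, mass_fraction = 0.5) {
  stopifnot(mass_fraction > 0, mass_fraction <= 1,
            all(per_site_counts >= 0))
  tot <- sum(per_site_counts)
  if (tot == 0) stop("all per-site counts are zero", call. = FALSE)
  cum <- cumsum(sort(per_site_counts, decreasing = TRUE))
  k <- which(cum >= mass_fraction * tot)[1]
  k / length(per_site_counts)
}
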