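# End-to-end orchestration: gold typing expansion, genotype comparison,
# frequency statistics, site classification, direction test, mapping-bias
# windows and coverage correlates, for one locus or a whole exon map.

#' Expand gold typings into per-copy consensus sequences
#'
#' Each individual's two allele calls are parsed and expanded against the
#' catalog ([expand_call_to_consensus()]); expansion is memoised per distinct
#' call string.
#'
#' @param gold gold typing tibble for ONE locus (`sample_id`, `population`,
#'   `allele_call_1`, `allele_call_2`).
#' @param catalog an [allele_catalog()].
#' @return List with `copies` (character matrix, `2 * n_individuals` rows x
#'   cds_length, base-set strings; copy 1 rows then copy 2 rows) and `meta`
#'   (tibble: `sample_id`, `population`, `copy`).
#' @export
expand_gold_typings <- function(gold, catalog) {
  calls <- unique(c(gold$allele_call_1, gold$allele_call_2))
  cons <- lapply(calls, function(cl) {
    expand_call_to_consensus(parse_allele_call(cl), catalog)
  })
  names(cons) <- calls
  n <- nrow(gold)
  copies <- do.call(rbind, c(cons[gold$allele_call_1],
                             cons[gold$allele_call_2]))
  meta <- tibble::tibble(
    sample_id = rep(gold$sample_id, 2),
    population = rep(gold$population, 2),
    copy = rep(1:2, each = n))
  list(copies = copies, meta = meta)
}

#' Deconstruct expanded gold typings into genotypes at given sites
#'
#' @param expanded output of [expand_gold_typings()].
#' @param sites integer vector of CDS positions.
#' @return Tibble: `sample_id`, `population`, `site`, `gold1`, `gold2`.
#' @export
gold_site_genotypes <- function(expanded, sites) {
  n <- nrow(expanded$copies) / 2L
  c1 <- expanded$copies[seq_len(n), sites, drop = FALSE]
  c2 <- expanded$copies[n + seq_len(n), sites, drop = FALSE]
  tibble::tibble(
    sample_id = rep(expanded$meta$sample_id[seq_len(n)], length(sites)),
    population = rep(expanded$meta$population[seq_len(n)], length(sites)),
    site = rep(as.integer(sites), each = n),
    gold1 = as.vector(c1), gold2 = as.vector(c2))
}

#' Run the full benchmark for one locus
#'
#' Comparison -> frequency statistics -> classification and flagging ->
#' direction test -> mapping-bias windows -> coverage correlates.
#'
#' @param gold gold typing tibble for the locus.
#' @param ngs NGS genotype tibble for the locus (`sample_id`, `site`, `ref`,
#'   `alt`, `ngs1`, `ngs2`).
#' @param catalog an [allele_catalog()] for the locus.
#' @param locus the [locus_spec()] (supplies the index sequence).
#' @param depth optional depth tibble (`sample_id`, `site`, `depth`).
#' @param fe_large,fe_well,min_pops thresholds for classification and
#'   flagging.
#' @param half_width window flank length.
#' @return A `refbias_result` list; see the elements documented in the
#'   package vignette.
#' @export
run_locus_pipeline <- function(gold, ngs, catalog, locus, depth = NULL,
                               fe_large = 0.1, fe_well = 0.01, min_pops = 2,
                               half_width = 25) {
  sites <- dplyr::distinct(ngs[, c("site", "ref", "alt")])
  sites <- sites[order(sites$site), , drop = FALSE]

  expanded <- expand_gold_typings(gold, catalog)
  gold_gt <- gold_site_genotypes(expanded, sites$site)
  gt <- dplyr::inner_join(gold_gt,
                          ngs[, c("sample_id", "site", "ref", "alt",
                                  "ngs1", "ngs2")],
                          by = c("sample_id", "site"))
  gt$locus <- locus$locus_id
  results <- compare_genotypes(gt)

  mm <- mismatch_summary(results)
  conc <- mismatch_concentration(mm$per_site$n_mismatch)

  freq <- frequency_table(results)
  freq$class <- classify_site(freq$fe, fe_large, fe_well)
  per_pop <- freq[freq$population != "global", , drop = FALSE]
  glob <- freq[freq$population == "global", , drop = FALSE]
  flagged <- unreliable_sites(per_pop, threshold = fe_large,
                              min_pops = min_pops)
  freq$flagged <- freq$site %in% flagged$site
  glob$flagged <- glob$site %in% flagged$site

  locus_mae <- mae(glob$fe)
  n_ref_skew <- sum(glob$flagged & glob$fe > 0)
  n_alt_skew <- sum(glob$flagged & glob$fe < 0)
  direction_p <- if (n_ref_skew + n_alt_skew >= 1) {
    direction_test(n_ref_skew, n_alt_skew)
  } else NA_real_

  h <- heterozygosity(glob$f_gold)
  cor_h_fe <- cor_h_absfe <- cor_mm_absfe <- NULL
  if (nrow(glob) >= 3 && stats::sd(h) > 0 && stats::sd(glob$fe) > 0) {
    cor_h_fe <- pearson_with_p(h, glob$fe)
    cor_h_absfe <- pearson_with_p(h, abs(glob$fe))
  }
  mm_rate <- mm$per_site$mismatch_rate[match(glob$site, mm$per_site$site)]
  if (nrow(glob) >= 3 && stats::sd(mm_rate) > 0 && stats::sd(abs(glob$fe)) > 0) {
    cor_mm_absfe <- pearson_with_p(mm_rate, abs(glob$fe))
  }
  h_report <- heterozygosity_filter_report(
    glob[, c("site", "f_gold")], flagged)

  windows <- build_window_table(expanded, results, sites, locus,
                                glob[, c("site", "class")], half_width)
  bias <- bias_mechanism_report(windows)

  coverage <- NULL
  if (!is.null(depth)) {
    cov_match <- coverage_by_match_status(depth, results)
    site_depth <- dplyr::summarise(
      dplyr::group_by(depth[depth$site %in% glob$site, ], site),
      mean_depth = mean(depth), .groups = "drop")
    j <- dplyr::inner_join(site_depth, glob[, c("site", "fe")], by = "site")
    cov_fe <- if (nrow(j) >= 3 && stats::sd(j$mean_depth) > 0 &&
                  stats::sd(abs(j$fe)) > 0) {
      coverage_vs_fe(j$mean_depth, abs(j$fe))
    } else NULL
    coverage <- list(by_match = cov_match, vs_fe = cov_fe,
                     site_depth = site_depth)
  }

  structure(list(
    locus_id = locus$locus_id,
    results = results, mismatch = mm, mismatch_concentration = conc,
    frequencies = freq, flagged = flagged,
    mae = locus_mae,
    direction = list(n_ref = n_ref_skew, n_alt = n_alt_skew, p = direction_p),
    heterozygosity = list(h = h, cor_h_fe = cor_h_fe,
                          cor_h_absfe = cor_h_absfe,
                          cor_mismatch_absfe = cor_mm_absfe,
                          filter_report = h_report),
    windows = windows, bias = bias, coverage = coverage),
    class = "refbias_result")
}

# Per-copy windows at every analysed SNP, with the ambiguity correction from
# the genotype comparison written back into the copy sequences.
build_window_table <- function(expanded, results, sites, locus,
                               site_classes, half_width = 25) {
  copies <- expanded$copies
  n <- nrow(copies) / 2L
  key <- paste(expanded$meta$sample_id[seq_len(n)])
  amb <- results[results$corrected, , drop = FALSE]
  if (nrow(amb) > 0L) {
    row_i <- match(amb$sample_id, key)
    copies[cbind(row_i, amb$site)] <- amb$gold1
    copies[cbind(n + row_i, amb$site)] <- amb$gold2
  }
  index_seq <- strsplit(locus$reference_ars_seq, "", fixed = TRUE)[[1]]
  counts <- window_mismatch_counts(copies, index_seq, sites$site,
                                   half_width = half_width,
                                   include_central = FALSE)
  centre <- copies[, sites$site, drop = FALSE]
  cls <- ifelse(grepl("/", centre, fixed = TRUE), NA_character_,
                ifelse(centre == rep(sites$ref, each = nrow(copies)),
                       "REF", "ALT"))
  tab <- tibble::tibble(
    locus = locus$locus_id,
    sample_id = rep(expanded$meta$sample_id, ncol(counts)),
    copy = rep(expanded$meta$copy, ncol(counts)),
    site = rep(sites$site, each = nrow(copies)),
    central_class = as.vector(cls),
    mismatch_count = as.vector(counts))
  tab$site_class <- site_classes$class[match(tab$site, site_classes$site)]
  tab
}

#' Run the full benchmark from files
#'
#' Reads the exon map, allele catalog, gold typings, VCF and (optionally)
#' depth table, runs [run_locus_pipeline()] for every locus present in both
#' the exon map and the data, and writes tidy TSV outputs.
#'
#' @param vcf,gold,catalog,exon_map,depth input file paths (`depth` may be
#'   `NULL`).
#' @param out_dir output directory for the TSV tables (`NULL` = don't
#'   write).
#' @param ... thresholds passed to [run_locus_pipeline()].
#' @return Named list of `refbias_result` objects (one per locus), with a
#'   `summary` tibble attached as an attribute.
#' @export
run_full_pipeline <- function(vcf, gold, catalog, exon_map, depth = NULL,
                              out_dir = NULL, ...) {
  specs <- read_exon_map(exon_map)
  cat <- read_allele_catalog(catalog)
  gold_tab <- read_gold_typings(gold)
  ngs_tab <- read_vcf_ars_sites(vcf, specs)
  depth_tab <- if (!is.null(depth)) read_depth_table(depth, specs) else NULL

  loci <- intersect(names(specs), unique(gold_tab$locus))
  loci <- intersect(loci, unique(ngs_tab$locus))
  if (length(loci) == 0L) stop("no locus shared by exon map, gold and VCF",
                               call. = FALSE)
  out <- list()
  for (lc in loci) {
    out[[lc]] <- run_locus_pipeline(
      gold = gold_tab[gold_tab$locus == lc, , drop = FALSE],
      ngs = ngs_tab[ngs_tab$locus == lc, , drop = FALSE],
      catalog = cat[cat$locus == specs[[lc]]$locus_id, , drop = FALSE],
      locus = specs[[lc]],
      depth = if (!is.null(depth_tab))
        depth_tab[depth_tab$locus == lc, , drop = FALSE] else NULL,
      ...)
  }
  summary_tab <- summarise_results(out)
  attr(out, "summary") <- summary_tab
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' One-row-per-locus summary of pipeline results
#'
#' @param results named list of `refbias_result` objects.
#' @return Tibble with mismatch, MAE, flagging, direction-test and
#'   window-test summaries per locus.
#' @export
summarise_results <- function(results) {
  dplyr::bind_rows(lapply(results, function(r) {
    over <- r$bias$tests[r$bias$tests$site_class == "overestimated", ]
    tibble::tibble(
      locus = r$locus_id,
      n_comparisons = r$mismatch$n_comparisons,
      mismatch_rate = r$mismatch$overall,
      mismatch_concentration_50 = r$mismatch_concentration,
      n_sites = sum(r$frequencies$population == "global"),
      mae = r$mae,
      n_flagged = nrow(r$flagged),
      n_ref_skewed = r$direction$n_ref,
      n_alt_skewed = r$direction$n_alt,
      direction_p = r$direction$p,
      over_mean_alt = if (nrow(over)) over$mean_alt else NA_real_,
      over_mean_ref = if (nrow(over)) over$mean_ref else NA_real_,
      over_p = if (nrow(over)) over$p else NA_real_)
  }))
}

write_pipeline_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f),
                                       progress = FALSE)
  w(dplyr::bind_rows(lapply(results, `[[`, "results")), "comparisons.tsv")
  w(dplyr::bind_rows(lapply(results, function(r) r$mismatch$per_site)),
    "mismatch_per_site.tsv")
  w(dplyr::bind_rows(lapply(results, function(r) {
    x <- r$mismatch$per_individual; x$locus <- r$locus_id; x
  })), "mismatch_per_individual.tsv")
  w(dplyr::bind_rows(lapply(results, `[[`, "frequencies")),
    "frequency_table.tsv")
  w(dplyr::bind_rows(lapply(results, `[[`, "flagged")), "flagged_sites.tsv")
  w(dplyr::bind_rows(lapply(results, function(r) {
    x <- r$windows; x$window_len <- NULL; x
  })), "windows.tsv")
  w(dplyr::bind_rows(lapply(results, function(r) {
    x <- r$bias$tests; if (nrow(x)) x$locus <- r$locus_id; x
  })), "window_tests.tsv")
  w(summarise_results(results), "summary.tsv")
  invisible(out_dir)
}
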