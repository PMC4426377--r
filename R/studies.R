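# Replicate-study helpers: run the full benchmark on one simulated dataset
# and extract the focal-site metrics used for calibration and
# mechanism-recovery studies.

#' Benchmark one simulated replicate and extract focal-site metrics
#'
#' Simulates a dataset under `config`, runs [run_locus_pipeline()] on it and
#' returns the quantities tracked across replicates: pooled FE at the focal
#' sites, the copy-weighted window mismatch differential, the rank-sum
#' p-value computed on one haplotype per allele lineage (the exchangeable
#' unit under the no-bias null: copy-weighted windows duplicate haplotypes,
#' and derived alleles duplicate their founder's flanking content, so both
#' would overstate the effective sample size; the pipeline still reports
#' copy-weighted windows for the per-site summaries), and the across-site
#' correlation between gold heterozygosity and FE.
#'
#' @param config a [sim_config()].
#' @return List with `fe_focal` (named by site), `window_diff`
#'   (mean ALT - mean REF mismatches per focal site, copy-weighted),
#'   `ranksum_p` (per focal site, distinct-haplotype windows), `h_fe_r`
#'   (Pearson r of gold H vs FE over all sites; `NA` if degenerate) and
#'   `result` (the full `refbias_result`).
#' @export
simulate_and_benchmark <- function(config) {
  sim <- suppressWarnings(simulate_dataset(config))
  r <- run_locus_pipeline(sim$gold, sim$ngs, sim$pool$catalog,
                          sim$pool$locus)
  glob <- r$frequencies[r$frequencies$population == "global", ]
  focal <- intersect(config$focal_sites$site, glob$site)
  fe_focal <- glob$fe[match(focal, glob$site)]
  names(fe_focal) <- focal

  wdiff <- ranksum <- rep(NA_real_, length(focal))
  names(wdiff) <- names(ranksum) <- focal
  present <- sort(unique(as.vector(
    sim$truth$allele_idx[!sim$truth$missing, , drop = FALSE])))
  # one representative haplotype per founder lineage among sampled alleles
  present <- present[!duplicated(sim$pool$lineage[present])]
  amat <- sim$pool$seq_mat[present, , drop = FALSE]
  acnt <- window_mismatch_counts(amat, sim$pool$ref_seq, as.integer(focal),
                                 half_width = config$half_width)
  for (k in seq_along(focal)) {
    s <- as.integer(focal[k])
    w <- r$windows[r$windows$site == s & !is.na(r$windows$central_class), ]
    if (length(unique(w$central_class)) == 2L) {
      wdiff[k] <- mean(w$mismatch_count[w$central_class == "ALT"]) -
        mean(w$mismatch_count[w$central_class == "REF"])
    }
    is_ref <- amat[, s] == sim$pool$ref_seq[s]
    if (any(is_ref) && !all(is_ref)) {
      ranksum[k] <- mannwhitney_one_tailed(acnt[!is_ref, k], acnt[is_ref, k])
    }
  }
  h <- heterozygosity(glob$f_gold)
  h_fe_r <- if (stats::sd(h) > 0 && stats::sd(glob$fe) > 0) {
    pearson_with_p(h, glob$fe)$r
  } else NA_real_
  list(fe_focal = fe_focal, window_diff = wdiff, ranksum_p = ranksum,
       h_fe_r = h_fe_r, result = r)
}

#' Run a replicate study over seeds (and optionally a lambda grid)
#'
#' @param config_base a [sim_config()]; its `seed` is replaced per
#'   replicate.
#' @param n_reps number of replicates.
#' @param seed0 base seed; replicate i uses `seed0 + i` (shared across
#'   lambda values so the grid is coupled).
#' @param lambdas optional numeric vector of mapping-loss rates; when given,
#'   every replicate is run at each value.
#' @return Tibble with one row per replicate (x lambda): `rep`, `lambda`,
#'   `mean_fe_focal`, `mean_window_diff`, `reject_05` (fraction of focal
#'   rank-sum p-values < 0.05), `h_fe_r`.
#' @export
replicate_study <- function(config_base, n_reps, seed0 = 1000L,
                            lambdas = NULL) {
  grid <- expand.grid(rep = seq_len(n_reps),
                      lambda = if (is.null(lambdas)) config_base$lambda
                               else lambdas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config_base
    cfg$seed <- as.integer(seed0 + 7L * grid$rep[i])
    cfg$lambda <- grid$lambda[i]
    m <- simulate_and_benchmark(cfg)
    tibble::tibble(
      rep = grid$rep[i], lambda = grid$lambda[i],
      mean_fe_focal = mean(m$fe_focal),
      mean_window_diff = mean(m$window_diff, na.rm = TRUE),
      frac_fe_gt = mean(m$fe_focal > 0.1),
      reject_05 = mean(m$ranksum_p < 0.05, na.rm = TRUE),
      n_tests = sum(!is.na(m$ranksum_p)),
      n_focal = length(m$fe_focal),
      h_fe_r = m$h_fe_r)
  })
  dplyr::bind_rows(rows)
}
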