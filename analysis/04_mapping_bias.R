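#!/usr/bin/env Rscript
# Step 4: the mapping-bias window test and the loss-rate dose response.
#
# 51-bp windows centred on each SNP are taken from every chromosome copy in
# the cohort and compared with the reference index sequence (central SNP
# excluded). If reference mapping bias drives the frequency errors, windows
# carrying the ALT allele at overestimated sites should bear more flanking
# mismatches than REF windows. A small replicate study then traces mean
# focal-site FE across mapping-loss rates.

suppressMessages(library(refbias))

res <- suppressMessages(run_full_pipeline(
  vcf = "results/data/ngs_calls.vcf",
  gold = "results/data/gold_typings.tsv",
  catalog = "results/data/allele_catalog.fasta",
  exon_map = "results/data/exon_map.json",
  out_dir = "results/mapbias"))
r <- res[[1]]

cat("Window mismatch means by site class (one-tailed rank-sum, ALT > REF):\n")
t <- r$bias$tests
for (i in seq_len(nrow(t))) {
  cat(sprintf("  %-14s ALT %.2f (n=%d) vs REF %.2f (n=%d), p = %.3g\n",
              t$site_class[i], t$mean_alt[i], t$n_alt[i],
              t$mean_ref[i], t$n_ref[i], t$p[i]))
}

cat("\nDose response of focal-site FE to the mapping-loss rate lambda\n")
cfg <- sim_config(n_individuals = 93, n_populations = 10)
st <- replicate_study(cfg, n_reps = 20, seed0 = 4000,
                      lambdas = c(0, 0.1, 0.3, 0.6, 1.0))
curve <- aggregate(mean_fe_focal ~ lambda, st, mean)
print(curve, row.names = FALSE)
readr::write_tsv(st, "results/mapbias/lambda_dose_response.tsv",
                 progress = FALSE)
cat("Tables written under results/mapbias/\n")
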