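# The generator is first-class code: its contracts (determinism, the
# mapping-loss limits, linkage construction) are tested like any module.

small_cfg <- function(...) {
  sim_config(seed = 101, n_alleles = 12, n_individuals = 40,
             n_populations = 2, L = 200,
             focal_sites = data.frame(site = c(60L, 140L), delta = 3L), ...)
}

test_that("the pool is deterministic under a fixed seed", {
  p1 <- simulate_allele_pool(small_cfg())
  p2 <- simulate_allele_pool(small_cfg())
  expect_identical(p1$catalog$seq, p2$catalog$seq)
  expect_identical(p1$sites, p2$sites)
  p3 <- simulate_allele_pool(sim_config(
    seed = 202, n_alleles = 12, L = 200,
    focal_sites = data.frame(site = c(60L, 140L), delta = 3L)))
  expect_false(identical(p1$catalog$seq, p3$catalog$seq))
})

test_that("pool structure: focal linkage places delta flanking variants", {
  cfg <- small_cfg(snp_density = 0)  # no background noise
  pool <- simulate_allele_pool(cfg)
  for (fs in cfg$focal_sites$site) {
    j <- which(pool$sites$site == fs)
    alt_alleles <- pool$seq_mat[, fs] != pool$ref_seq[fs]
    expect_true(any(alt_alleles) && !all(alt_alleles))
    # windows centred on the focal site: ALT haplotypes carry exactly delta
    # extra flanking mismatches (central excluded)
    cnt <- window_mismatch_counts(pool$seq_mat, pool$ref_seq, fs,
                                  half_width = cfg$half_width)
    expect_true(all(cnt[alt_alleles, 1] == 3))
    expect_true(all(cnt[!alt_alleles, 1] == 0))
  }
  expect_error(sim_config(focal_sites = data.frame(site = 100L, delta = 60L)),
               "delta")
})

test_that("population sampling respects ambiguity and missing rates", {
  cfg <- small_cfg(ambiguity_rate = 0, missing_rate = 0)
  pool <- simulate_allele_pool(cfg)
  popn <- simulate_population(pool, cfg)
  expect_equal(nrow(popn$gold), 80)
  expect_false(any(grepl("/", c(popn$gold$allele_call_1,
                                popn$gold$allele_call_2))))

  cfg2 <- small_cfg(ambiguity_rate = 0.5, missing_rate = 0.2)
  pool2 <- simulate_allele_pool(cfg2)
  popn2 <- suppressWarnings(simulate_population(pool2, cfg2))
  expect_lt(nrow(popn2$gold), 80)
  amb <- grepl("/", popn2$gold$allele_call_1)
  expect_gt(mean(amb), 0.1)
  # ambiguity partners differ from the true allele at <= 2 sites
  for (cl in utils::head(popn2$gold$allele_call_1[amb], 5)) {
    nm <- strsplit(cl, "/", fixed = TRUE)[[1]]
    i <- match(nm, pool2$allele_names)
    expect_lte(pool2$dist[i[1], i[2]], 2)
  }
})

test_that("sampled allele frequencies converge to the Dirichlet draws", {
  cfg <- sim_config(seed = 77, n_alleles = 6, n_individuals = 8000,
                    n_populations = 1, L = 120,
                    focal_sites = data.frame(site = 60L, delta = 0L),
                    ambiguity_rate = 0, missing_rate = 0)
  pool <- simulate_allele_pool(cfg)
  popn <- simulate_population(pool, cfg)
  w <- popn$truth$weights[, 1]
  emp <- tabulate(popn$truth$allele_idx, nbins = 6) / (2 * 8000)
  se <- sqrt(w * (1 - w) / (2 * 8000))
  expect_true(all(abs(emp - w) <= 3 * se + 1e-9))
})

test_that("the no-noise limit reproduces true genotypes exactly", {
  cfg <- small_cfg(lambda = 0, epsilon = 0, mean_depth = 60,
                   ambiguity_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  truth_base <- function(copy) {
    sim$pool$seq_mat[sim$truth$allele_idx[, copy], sim$sites$site]
  }
  t1 <- as.vector(truth_base(1)); t2 <- as.vector(truth_base(2))
  got <- paste(pmin(sim$ngs$ngs1, sim$ngs$ngs2),
               pmax(sim$ngs$ngs1, sim$ngs$ngs2))
  want <- paste(pmin(t1, t2), pmax(t1, t2))
  expect_equal(got, want)
})

test_that("total mapping loss turns focal sites homozygous REF", {
  # lambda = 1 and delta >= 1: every ALT read carries >= 1 mismatch and is
  # lost; REF-only evidence (or no evidence) yields homozygous REF calls
  cfg <- small_cfg(lambda = 1, epsilon = 0, ambiguity_rate = 0,
                   missing_rate = 0)
  sim <- simulate_dataset(cfg)
  for (fs in cfg$focal_sites$site) {
    sub <- sim$ngs[sim$ngs$site == fs, ]
    expect_true(all(sub$ngs1 == sub$ref & sub$ngs2 == sub$ref))
    f_ngs <- ref_allele_frequency(sub$ngs1, sub$ngs2, sub$ref[1])
    expect_equal(f_ngs, 1.0)
  }
})

test_that("surviving-read depth decreases with the loss rate", {
  cfgs <- lapply(c(0, 0.5), function(l) small_cfg(lambda = l))
  sims <- suppressWarnings(lapply(cfgs, simulate_dataset))
  expect_gt(mean(sims[[1]]$depth$depth), mean(sims[[2]]$depth$depth))
})

test_that("fixture bundles round-trip through the package readers", {
  cfg <- small_cfg(ambiguity_rate = 0.2)
  sim <- suppressWarnings(simulate_dataset(cfg))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, dir)

  specs <- read_exon_map(paths$exon_map)
  expect_equal(names(specs), "A")
  expect_equal(specs$A$cds_length, 200)
  expect_equal(specs$A$reference_ars_seq,
               paste(sim$pool$ref_seq, collapse = ""))

  cat2 <- read_allele_catalog(paths$catalog)
  expect_equal(cat2$seq, sim$pool$catalog$seq)

  gold2 <- read_gold_typings(paths$gold)
  expect_equal(gold2$allele_call_1, sim$gold$allele_call_1)

  ngs2 <- suppressMessages(read_vcf_ars_sites(paths$vcf, specs))
  key <- function(d) paste(d$sample_id, d$site)
  m <- match(key(sim$ngs), key(ngs2))
  expect_false(any(is.na(m)))
  expect_equal(ngs2$ngs1[m], sim$ngs$ngs1)
  expect_equal(ngs2$ngs2[m], sim$ngs$ngs2)
  expect_equal(ngs2$ref[m], sim$ngs$ref)

  # VCF REF base equals the index base at each site
  expect_equal(sim$sites$ref, sim$pool$ref_seq[sim$sites$site])

  dep2 <- read_depth_table(paths$depth, specs)
  expect_equal(sum(dep2$depth), sum(sim$depth$depth))

  # byte-identical files under the same seed
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(suppressWarnings(simulate_dataset(cfg)), dir2)
  for (f in basename(unlist(paths))) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("minus-strand loci reverse-complement through the VCF round trip", {
  cfg <- small_cfg(strand = "-", ambiguity_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, dir)
  raw <- readLines(paths$vcf)
  body <- raw[!startsWith(raw, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_false(is.unsorted(pos))
  specs <- read_exon_map(paths$exon_map)
  ngs2 <- suppressMessages(read_vcf_ars_sites(paths$vcf, specs))
  key <- function(d) paste(d$sample_id, d$site)
  m <- match(key(sim$ngs), key(ngs2))
  expect_equal(ngs2$ref[m], sim$ngs$ref)  # back in CDS orientation
  expect_equal(ngs2$ngs1[m], sim$ngs$ngs1)
})
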