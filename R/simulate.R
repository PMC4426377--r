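# Synthetic gold-standard + NGS data with a per-read mapping-loss model.
#
# The generator emulates the structure the benchmark assumes: an IMGT-style
# allele catalog over a synthetic ARS sequence, diploid population samples
# typed with configurable ambiguity, and an NGS caller whose errors arise
# from reads that fail to map in proportion to their mismatches against the
# reference index. Focal sites can carry extra flanking variants linked to
# their ALT allele (delta), the linkage that drives reference mapping bias.

#' Simulation configuration
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param locus_id locus designator used for allele names.
#' @param L ARS CDS length in bp (546 = class I exons 2+3; 270 = class II
#'   exon 2).
#' @param class `"I"` or `"II"` (drives the two-exon vs one-exon map).
#' @param strand genomic strand of the simulated locus.
#' @param n_alleles size of the allele pool (HLA loci carry tens to hundreds
#'   of alleles; ~30% of pool alleles are near copies of another allele,
#'   differing at 1-2 sites, mimicking synonymous/noncoding allele groups).
#' @param n_individuals diploid individuals per population.
#' @param n_populations number of populations.
#' @param snp_density per-position probability of a background polymorphic
#'   site in the pool.
#' @param focal_sites data frame with columns `site`, `delta` (extra
#'   ALT-linked flanking variants within `half_width`) and optionally `alt`.
#' @param concentration symmetric Dirichlet concentration for population
#'   allele frequencies.
#' @param mean_depth expected reads covering a site per individual before
#'   mapping loss (Poisson; each chromosome copy contributes half).
#' @param half_width read/window flank length (reads span `2*half_width+1`).
#' @param lambda per-mismatch read-loss probability: a read with `m`
#'   mismatches to the index maps with probability `(1-lambda)^m`.
#' @param epsilon per-read base-call error rate at the focal site.
#' @param ambiguity_rate probability a gold allele call is reported as an
#'   ambiguity set (the true allele plus a catalog allele within 2
#'   differences).
#' @param missing_rate probability a gold typing is missing for an
#'   individual.
#' @param zero_read_call genotype emitted when no reads survive: `"ref"`
#'   (homozygous reference, mimicking reference-biased integrated call sets)
#'   or `"missing"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       locus_id = "A",
                       L = 546L,
                       class = "I",
                       strand = "+",
                       n_alleles = 60L,
                       n_individuals = 78L,
                       n_populations = 12L,
                       snp_density = 0.12,
                       focal_sites = data.frame(site = c(132L, 244L, 400L),
                                                delta = 3L),
                       concentration = 1,
                       mean_depth = 8,
                       half_width = 25L,
                       lambda = 0.3,
                       epsilon = 0.005,
                       ambiguity_rate = 0.1,
                       missing_rate = 0.02,
                       zero_read_call = c("ref", "missing")) {
  zero_read_call <- match.arg(zero_read_call)
  cfg <- list(seed = as.integer(seed), locus_id = locus_id, L = as.integer(L),
              class = class, strand = strand,
              n_alleles = as.integer(n_alleles),
              n_individuals = as.integer(n_individuals),
              n_populations = as.integer(n_populations),
              snp_density = snp_density,
              focal_sites = as.data.frame(focal_sites),
              concentration = concentration, mean_depth = mean_depth,
              half_width = as.integer(half_width), lambda = lambda,
              epsilon = epsilon, ambiguity_rate = ambiguity_rate,
              missing_rate = missing_rate, zero_read_call = zero_read_call)
  rates <- c(cfg$snp_density, cfg$lambda, cfg$epsilon, cfg$ambiguity_rate,
             cfg$missing_rate)
  stopifnot(all(rates >= 0 & rates <= 1), cfg$L >= 2L * cfg$half_width + 1L,
            cfg$strand %in% c("+", "-"), cfg$class %in% c("I", "II"),
            cfg$n_alleles >= 2L, cfg$mean_depth >= 0)
  if (nrow(cfg$focal_sites) > 0) {
    stopifnot(all(cfg$focal_sites$site >= 1 & cfg$focal_sites$site <= cfg$L))
    if (any(cfg$focal_sites$delta > 2L * cfg$half_width)) {
      stop("focal delta exceeds 2 * half_width", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# Default two-exon (class I) / one-exon (class II) genomic map. Coding-order
# exons have decreasing genomic coordinates on the "-" strand.
sim_locus_spec <- function(config, ref_seq_string) {
  if (config$class == "I") {
    len1 <- min(270L, config$L %/% 2L)  # 270 at the canonical L = 546
    len2 <- config$L - len1
    stopifnot(len2 > 0L)
    exons <- if (config$strand == "+") {
      data.frame(label = c("exon2", "exon3"),
                 start = c(1000L, 2000L),
                 end = c(1000L + len1 - 1L, 2000L + len2 - 1L))
    } else {
      data.frame(label = c("exon2", "exon3"),
                 start = c(2000L, 1000L),
                 end = c(2000L + len1 - 1L, 1000L + len2 - 1L))
    }
  } else {
    exons <- data.frame(label = "exon2", start = 1000L,
                        end = 1000L + config$L - 1L)
  }
  locus_spec(config$locus_id, exons, strand = config$strand,
             class = config$class, reference_ars_seq = ref_seq_string)
}

#' Simulate an allele pool and catalog
#'
#' Draws a uniform-random reference (index) ARS sequence, background
#' polymorphic sites at `snp_density` with per-site ALT carriage
#' probabilities drawn from U(0.1, 0.5), and a pool in which roughly 30% of
#' alleles are near copies of another allele (1-2 differences), mimicking
#' the fine-grained structure of HLA nomenclature and providing partners for
#' ambiguous typing. At each focal site, ALT-carrying alleles also carry
#' `delta` shared extra variants within `half_width` of the site.
#'
#' @param config a [sim_config()].
#' @return List with `catalog` ([allele_catalog()]), `locus`
#'   ([locus_spec()]), `seq_mat` (alleles x L character matrix), `ref_seq`
#'   (character vector), `sites` (tibble: site, ref, alt, type), `dist`
#'   (allele x allele difference-count matrix) and `lineage` (founder index
#'   per allele: derived alleles share their parent's lineage).
#' @export
simulate_allele_pool <- function(config) {
  set.seed(config$seed)
  L <- config$L
  ref_seq <- sample(BASES, L, replace = TRUE)
  foc <- config$focal_sites
  n_foc <- nrow(foc)
  foc_alt <- if (n_foc > 0 && !is.null(foc$alt)) as.character(foc$alt)
             else rep(NA_character_, n_foc)
  for (i in seq_len(n_foc)) {
    if (is.na(foc_alt[i])) {
      foc_alt[i] <- sample(setdiff(BASES, ref_seq[foc$site[i]]), 1)
    }
  }
  bg_pos <- setdiff(which(stats::runif(L) < config$snp_density),
                    foc$site)
  sites <- tibble::tibble(
    site = c(as.integer(foc$site), bg_pos),
    alt = c(foc_alt,
            vapply(bg_pos, function(s) sample(setdiff(BASES, ref_seq[s]), 1), "")),
    q = c(rep(0.5, n_foc), stats::runif(length(bg_pos), 0.1, 0.5)),
    type = c(rep("focal", n_foc), rep("background", length(bg_pos)))
  )
  # linked flanking variants: one set per focal site, carried by its ALT alleles
  used <- sites$site
  linked_of <- vector("list", n_foc)
  for (i in seq_len(n_foc)) {
    d <- foc$delta[i]
    if (d == 0) { linked_of[[i]] <- integer(0); next }
    cand <- setdiff(max(1L, foc$site[i] - config$half_width):
                      min(L, foc$site[i] + config$half_width), used)
    if (length(cand) < d) {
      stop("not enough free positions for delta linked variants near site ",
           foc$site[i], call. = FALSE)
    }
    pos <- sort(sample(cand, d))
    linked_of[[i]] <- pos
    used <- c(used, pos)
    sites <- dplyr::bind_rows(sites, tibble::tibble(
      site = pos,
      alt = vapply(pos, function(s) sample(setdiff(BASES, ref_seq[s]), 1), ""),
      q = NA_real_, type = "linked"))
  }
  sites <- sites[order(sites$site), , drop = FALSE]

  n_core <- max(2L, ceiling(0.7 * config$n_alleles))
  n_der <- config$n_alleles - n_core
  togglable <- which(sites$type == "background")
  # carriage matrix over the focal+background columns
  carry <- matrix(FALSE, config$n_alleles, nrow(sites))
  for (j in seq_len(nrow(sites))) {
    if (sites$type[j] == "linked") next
    carry[seq_len(n_core), j] <- stats::runif(n_core) < sites$q[j]
  }
  # focal sites must segregate in the pool
  for (i in seq_len(n_foc)) {
    j <- which(sites$site == foc$site[i])
    col <- carry[seq_len(n_core), j]
    if (all(col)) carry[sample(n_core, 1), j] <- FALSE
    if (!any(col)) carry[sample(n_core, 1), j] <- TRUE
  }
  parent <- rep(NA_integer_, config$n_alleles)
  for (k in seq_len(n_der)) {
    a <- n_core + k
    p <- sample(n_core, 1)
    parent[a] <- p
    carry[a, ] <- carry[p, ]
    if (length(togglable) > 0) {
      tog <- sample(togglable, min(sample(1:2, 1), length(togglable)))
      carry[a, tog] <- !carry[a, tog]
    }
  }
  # linked columns follow the focal carriage of each allele
  for (i in seq_len(n_foc)) {
    jf <- which(sites$site == foc$site[i])
    for (pos in linked_of[[i]]) {
      carry[, which(sites$site == pos)] <- carry[, jf]
    }
  }

  seq_mat <- matrix(rep(ref_seq, each = config$n_alleles),
                    nrow = config$n_alleles)
  for (j in seq_len(nrow(sites))) {
    seq_mat[carry[, j], sites$site[j]] <- sites$alt[j]
  }

  # IMGT-style names: core i -> LOCUS*ii:01, derived -> parent's group with
  # an incremented synonymous field
  syn <- rep(1L, config$n_alleles)
  names_out <- character(config$n_alleles)
  for (a in seq_len(config$n_alleles)) {
    if (is.na(parent[a])) {
      names_out[a] <- format_allele_name(config$locus_id, c(a, 1L))
    } else {
      syn[parent[a]] <- syn[parent[a]] + 1L
      names_out[a] <- format_allele_name(config$locus_id,
                                         c(parent[a], syn[parent[a]]))
    }
  }
  dist <- as.matrix(stats::dist(carry * 1, method = "manhattan"))
  seqs <- apply(seq_mat, 1, paste, collapse = "")
  list(catalog = allele_catalog(names_out, seqs),
       locus = sim_locus_spec(config, paste(ref_seq, collapse = "")),
       seq_mat = seq_mat, ref_seq = ref_seq,
       allele_names = names_out, sites = sites, dist = dist,
       lineage = ifelse(is.na(parent), seq_along(parent), parent))
}

#' Simulate diploid population samples and their gold typings
#'
#' Population allele frequencies are symmetric-Dirichlet draws over the pool;
#' individuals sample two alleles independently. With probability
#' `ambiguity_rate` a call is reported as an ambiguity set (true allele plus
#' a catalog allele differing at <= 2 sites; skipped with a warning when no
#' such partner exists), and with probability `missing_rate` the typing is
#' absent.
#'
#' @param pool output of [simulate_allele_pool()].
#' @param config the [sim_config()].
#' @return List with `gold` (tibble: sample_id, population, locus,
#'   allele_call_1, allele_call_2) and `truth` (allele indices, population
#'   labels, missing flags, pool weights and expected per-site REF
#'   frequencies).
#' @export
simulate_population <- function(pool, config) {
  set.seed(config$seed + 1L)
  nA <- config$n_alleles
  n_pop <- config$n_populations
  n_ind <- config$n_individuals
  N <- n_pop * n_ind
  w <- matrix(stats::rgamma(nA * n_pop, shape = config$concentration),
              nrow = nA)
  w <- sweep(w, 2, colSums(w), "/")
  pops <- rep(sprintf("POP%02d", seq_len(n_pop)), each = n_ind)
  allele_idx <- matrix(0L, N, 2)
  for (p in seq_len(n_pop)) {
    rows <- which(pops == sprintf("POP%02d", p))
    allele_idx[rows, ] <- sample(nA, 2 * n_ind, replace = TRUE,
                                 prob = w[, p])
  }
  sample_ids <- sprintf("S%04d", seq_len(N))
  missing <- stats::runif(N) < config$missing_rate

  near <- lapply(seq_len(nA), function(a) {
    which(pool$dist[a, ] <= 2 & seq_len(nA) != a)
  })
  n_skipped <- 0L
  call_of <- function(a) {
    if (stats::runif(1) < config$ambiguity_rate) {
      if (length(near[[a]]) == 0L) {
        n_skipped <<- n_skipped + 1L
        return(pool$allele_names[a])
      }
      partner <- if (length(near[[a]]) == 1L) near[[a]] else sample(near[[a]], 1)
      return(paste(sort(pool$allele_names[c(a, partner)]), collapse = "/"))
    }
    pool$allele_names[a]
  }
  call1 <- vapply(allele_idx[, 1], call_of, "")
  call2 <- vapply(allele_idx[, 2], call_of, "")
  if (n_skipped > 0L) {
    warning(n_skipped, " ambiguity request(s) skipped: no catalog allele ",
            "within 2 differences", call. = FALSE)
  }
  gold <- tibble::tibble(
    sample_id = sample_ids[!missing],
    population = pops[!missing],
    locus = config$locus_id,
    allele_call_1 = call1[!missing],
    allele_call_2 = call2[!missing])

  sites <- pool$sites
  is_ref <- t(pool$seq_mat[, sites$site, drop = FALSE] ==
                rep(pool$ref_seq[sites$site], each = nA))  # sites x alleles
  f_true <- is_ref %*% w  # sites x pops
  freqs <- tibble::tibble(
    site = rep(sites$site, n_pop),
    population = rep(sprintf("POP%02d", seq_len(n_pop)), each = nrow(sites)),
    f_ref_true = as.vector(f_true))
  glob <- tibble::tibble(site = sites$site, population = "global",
                         f_ref_true = rowMeans(f_true))
  list(gold = gold,
       truth = list(sample_ids = sample_ids, populations = pops,
                    allele_idx = allele_idx, missing = missing,
                    weights = w, freqs = dplyr::bind_rows(freqs, glob)))
}

#' Simulate NGS genotype calls under the mapping-loss read model
#'
#' For every site that segregates among the sampled chromosome copies, each
#' copy contributes `Poisson(mean_depth / 2)` reads spanning
#' `2*half_width + 1` bases around the site (truncated at CDS edges). A read
#' whose haplotype carries `m` mismatches to the reference index within that
#' span -- the central site included, since the mapper does not know which
#' site is focal -- survives alignment with probability `(1 - lambda)^m`.
#' Surviving reads report the copy's base, flipped to a random other base
#' with probability `epsilon`. The genotype is the maximum-likelihood diploid
#' genotype over {REF,ALT} under the symmetric read-error model; individuals
#' with zero surviving reads are emitted per `zero_read_call`.
#'
#' @param pool output of [simulate_allele_pool()].
#' @param popn output of [simulate_population()].
#' @param config the [sim_config()].
#' @return List with `ngs` (tibble: sample_id, population, site, ref, alt,
#'   ngs1, ngs2), `depth` (tibble: sample_id, site, depth of surviving
#'   reads) and `sites` (tibble: site, ref, alt).
#' @export
simulate_ngs_calls <- function(pool, popn, config) {
  set.seed(config$seed + 2L)
  truth <- popn$truth
  N <- length(truth$sample_ids)
  idx_flat <- as.vector(truth$allele_idx)  # copy 1 block then copy 2 block
  base_all <- pool$seq_mat[idx_flat, pool$sites$site, drop = FALSE]
  ref_row <- pool$ref_seq[pool$sites$site]
  seg <- vapply(seq_len(nrow(pool$sites)), function(j) {
    b <- base_all[, j]
    any(b == ref_row[j]) && any(b != ref_row[j])
  }, logical(1))
  sites <- pool$sites[seg, c("site", "alt")]
  sites$ref <- pool$ref_seq[sites$site]
  S <- nrow(sites)
  if (S == 0L) stop("no segregating sites in the sample", call. = FALSE)

  mprime_allele <- window_mismatch_counts(
    pool$seq_mat, pool$ref_seq, sites$site,
    half_width = config$half_width, include_central = TRUE)
  mp <- mprime_allele[idx_flat, , drop = FALSE]          # 2N x S
  copy_base <- base_all[, seg, drop = FALSE]             # 2N x S
  copy_is_ref <- copy_base == rep(sites$ref, each = 2L * N)

  ncell <- 2L * N * S
  reads <- stats::rpois(ncell, config$mean_depth / 2)
  kept <- stats::rbinom(ncell, reads, (1 - config$lambda)^as.vector(mp))
  correct <- stats::rbinom(ncell, kept, 1 - config$epsilon)
  err <- kept - correct
  to_other_focal <- stats::rbinom(ncell, err, 1 / 3)
  n_ref_copy <- ifelse(as.vector(copy_is_ref), correct, to_other_focal)
  n_alt_copy <- ifelse(as.vector(copy_is_ref), to_other_focal, correct)
  dim(n_ref_copy) <- dim(n_alt_copy) <- dim(kept) <- c(2L * N, S)
  R <- n_ref_copy[seq_len(N), , drop = FALSE] + n_ref_copy[N + seq_len(N), , drop = FALSE]
  A <- n_alt_copy[seq_len(N), , drop = FALSE] + n_alt_copy[N + seq_len(N), , drop = FALSE]
  D <- kept[seq_len(N), , drop = FALSE] + kept[N + seq_len(N), , drop = FALSE]

  eps <- config$epsilon
  term <- function(n, p) ifelse(n == 0L, 0, n * log(p))
  ll_rr <- term(R, 1 - eps) + term(A, eps / 3)
  ll_het <- term(R + A, (1 - eps) / 2 + eps / 6)
  ll_aa <- term(A, 1 - eps) + term(R, eps / 3)
  g <- max.col(cbind(as.vector(ll_rr), as.vector(ll_het), as.vector(ll_aa)),
               ties.method = "first")  # 1=RR, 2=het, 3=AA
  zero <- as.vector(D) == 0L
  g[zero] <- if (config$zero_read_call == "ref") 1L else NA_integer_

  ref_v <- rep(sites$ref, each = N)
  alt_v <- rep(sites$alt, each = N)
  ngs <- tibble::tibble(
    sample_id = rep(truth$sample_ids, S),
    population = rep(truth$populations, S),
    site = rep(sites$site, each = N),
    ref = ref_v, alt = alt_v,
    ngs1 = dplyr::case_when(is.na(g) ~ NA_character_,
                            g == 3L ~ alt_v, TRUE ~ ref_v),
    ngs2 = dplyr::case_when(is.na(g) ~ NA_character_,
                            g == 1L ~ ref_v, TRUE ~ alt_v))
  depth <- tibble::tibble(
    sample_id = rep(truth$sample_ids, S),
    site = rep(sites$site, each = N),
    depth = as.vector(D))
  list(ngs = ngs, depth = depth, sites = tibble::as_tibble(sites))
}

#' Simulate a complete gold + NGS dataset
#'
#' Runs [simulate_allele_pool()], [simulate_population()] and
#' [simulate_ngs_calls()] under one seed.
#'
#' @param config a [sim_config()].
#' @return List with `config`, `pool`, `gold`, `truth`, `ngs`, `depth`,
#'   `sites`.
#' @export
simulate_dataset <- function(config) {
  pool <- simulate_allele_pool(config)
  popn <- simulate_population(pool, config)
  calls <- simulate_ngs_calls(pool, popn, config)
  list(config = config, pool = pool, gold = popn$gold, truth = popn$truth,
       ngs = calls$ngs, depth = calls$depth, sites = calls$sites)
}

#' Write a simulated dataset as a standard-format fixture bundle
#'
#' Emits a VCF (v4.2) of the NGS calls, a gold typing TSV, the allele
#' catalog as FASTA, the exon map as JSON (including the index sequence), a
#' per-base depth TSV (1-based genomic positions) and a truth TSV of
#' expected per-population REF frequencies. Re-ingesting the files through
#' the package readers reproduces the in-memory tables.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param chrom chromosome name used in the VCF and depth table.
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture_bundle <- function(sim, dir, chrom = "6") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    catalog = file.path(dir, "allele_catalog.fasta"),
    exon_map = file.path(dir, "exon_map.json"),
    gold = file.path(dir, "gold_typings.tsv"),
    vcf = file.path(dir, "ngs_calls.vcf"),
    depth = file.path(dir, "depth.tsv"),
    truth = file.path(dir, "truth_frequencies.tsv"))

  seqs <- Biostrings::DNAStringSet(sim$pool$catalog$seq)
  names(seqs) <- sim$pool$catalog$name
  Biostrings::writeXStringSet(seqs, paths$catalog)

  loc <- sim$pool$locus
  jsonlite::write_json(list(loci = list(list(
    locus_id = loc$locus_id, class = loc$class, strand = loc$strand,
    chrom = chrom,
    exons = loc$exons,
    reference_ars_seq = loc$reference_ars_seq))),
    paths$exon_map, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  readr::write_tsv(sim$gold, paths$gold, progress = FALSE)
  readr::write_tsv(sim$truth$freqs, paths$truth, progress = FALSE)

  gpos <- cds_to_genomic(loc, sim$depth$site)
  depth_tab <- tibble::tibble(sample_id = sim$depth$sample_id, chrom = chrom,
                              pos = gpos, depth = sim$depth$depth)
  readr::write_tsv(depth_tab[order(depth_tab$sample_id, depth_tab$pos), ],
                   paths$depth, progress = FALSE)

  write_sim_vcf(sim, paths$vcf, chrom)
  invisible(paths)
}

# VCF writer for simulated calls; REF/ALT are reverse-complemented into
# genomic orientation on "-" strand loci.
write_sim_vcf <- function(sim, path, chrom = "6") {
  loc <- sim$pool$locus
  sites <- sim$sites
  sites$pos <- cds_to_genomic(loc, sites$site)
  if (loc$strand == "-") {
    sites$ref_out <- rev_comp(sites$ref)
    sites$alt_out <- rev_comp(sites$alt)
  } else {
    sites$ref_out <- sites$ref
    sites$alt_out <- sites$alt
  }
  samples <- sim$truth$sample_ids
  gt <- matrix("./.", nrow(sites), length(samples))
  m <- sim$ngs
  code <- ifelse(is.na(m$ngs1), "./.",
                 paste0(as.integer(m$ngs1 != m$ref), "/",
                        as.integer(m$ngs2 != m$ref)))
  site_i <- match(m$site, sites$site)
  samp_i <- match(m$sample_id, samples)
  gt[cbind(site_i, samp_i)] <- code
  ord <- order(sites$pos)
  body <- cbind(chrom, sites$pos[ord], ".", sites$ref_out[ord],
                sites$alt_out[ord], ".", "PASS", ".", "GT",
                gt[ord, , drop = FALSE])
  header <- c("##fileformat=VCFv4.2",
              "##source=refbias_simulator",
              sprintf("##contig=<ID=%s>", chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
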