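# Shared fixture builders: tiny hand-made catalogs and genotype tables.

# catalog of short "alleles" over a 10-bp ARS; differences placed by hand
tiny_catalog <- function() {
  allele_catalog(
    names = c("B*35:02", "B*35:03:01", "B*35:03:02", "B*35:04"),
    seqs = c("ACGTACGTAC",   # B*35:02
             "ACGAACGTAC",   # B*35:03:01 (pos 4 T->A)
             "ACGAACGTAT",   # B*35:03:02 (pos 4 T->A, pos 10 C->T)
             "ACGTACGTCC"))  # B*35:04 (pos 9 A->C)
}

# two-exon "+"-strand locus: exon1 1000-1009 (len 10), exon2 2000-2005 (len 6)
plus_locus <- function(ref = NULL) {
  locus_spec("T1",
             data.frame(label = c("e1", "e2"),
                        start = c(1000L, 2000L), end = c(1009L, 2005L)),
             strand = "+", class = "II", reference_ars_seq = ref)
}

# single-exon "-"-strand locus 1000-1050
minus_locus <- function() {
  locus_spec("T2", data.frame(label = "e1", start = 1000L, end = 1050L),
             strand = "-", class = "II")
}

# random exon map with k exons and random strand, for round-trip properties
random_locus <- function(k = 3) {
  lens <- sample(5:40, k, replace = TRUE)
  gaps <- sample(10:100, k, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-k])) + 500L
  ex <- data.frame(label = paste0("e", 1:k), start = starts,
                   end = starts + lens - 1L)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") ex <- ex[rev(seq_len(k)), , drop = FALSE]
  locus_spec("R", ex, strand = strand, class = "II")
}

# a small base-set genotype table with known ambiguity structure
random_genotype_table <- function(n, p_amb = 0.3) {
  rand_set <- function() {
    if (stats::runif(1) < p_amb) base_set(sample(BASES_T, 2)) else sample(BASES_T, 1)
  }
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    site = 1L,
    gold1 = vapply(seq_len(n), function(i) rand_set(), ""),
    gold2 = vapply(seq_len(n), function(i) rand_set(), ""),
    ngs1 = sample(BASES_T, n, replace = TRUE),
    ngs2 = sample(BASES_T, n, replace = TRUE))
}

BASES_T <- c("A", "C", "G", "T")

# exhaustive pairing oracle for the match rule: try both assignments of NGS
# alleles to gold copies, each NGS base must sit in its gold copy's set
match_oracle <- function(gold, ngs) {
  sets <- lapply(gold, function(g) strsplit(g, "/", fixed = TRUE)[[1]])
  for (perm in list(c(1, 2), c(2, 1))) {
    ok <- ngs[1] %in% sets[[perm[1]]] && ngs[2] %in% sets[[perm[2]]]
    if (ok) return(TRUE)
  }
  FALSE
}

# all base sets of size 1 or 2 as canonical strings
all_small_sets <- function() {
  singles <- BASES_T
  pairs <- apply(utils::combn(BASES_T, 2), 2, paste, collapse = "/")
  c(singles, pairs)
}
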