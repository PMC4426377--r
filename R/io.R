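# Readers for the external formats: VCF genotype calls, gold typing TSV,
# allele-catalog FASTA, exon-map JSON and per-base depth tables.

#' Read an exon-map configuration
#'
#' JSON with a top-level `loci` array; each entry carries `locus_id`,
#' `class`, `strand`, `chrom`, `exons` (array of `label`/`start`/`end`,
#' 1-based inclusive) and `reference_ars_seq` (the index sequence over the
#' concatenated ARS exons in coding orientation).
#'
#' @param path JSON file path.
#' @return Named list of [locus_spec()] objects (names = locus ids), each
#'   with a `chrom` attribute.
#' @export
read_exon_map <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$loci)) stop("exon map lacks a 'loci' entry", call. = FALSE)
  out <- list()
  for (lc in cfg$loci) {
    exons <- do.call(rbind, lapply(lc$exons, function(e) {
      data.frame(label = e$label %||% NA_character_,
                 start = as.integer(e$start), end = as.integer(e$end))
    }))
    spec <- locus_spec(lc$locus_id, exons, strand = lc$strand %||% "+",
                       class = lc$class %||% "I",
                       reference_ars_seq = lc$reference_ars_seq)
    attr(spec, "chrom") <- as.character(lc$chrom %||% NA_character_)
    out[[lc$locus_id]] <- spec
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an allele catalog from FASTA
#'
#' Each header must be a full allele name (e.g. `>B*35:03:01`); sequences
#' are concatenated ARS exons in coding orientation.
#'
#' @param path FASTA file path.
#' @return An [allele_catalog()].
#' @export
read_allele_catalog <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  allele_catalog(names(ss), as.character(ss))
}

#' Read a gold typing table
#'
#' Tab-separated with columns `sample_id`, `population`, `locus`,
#' `allele_call_1`, `allele_call_2` (calls may be `/`-separated ambiguity
#' lists).
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_gold_typings <- function(path) {
  gold <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  need <- c("sample_id", "locus", "allele_call_1", "allele_call_2")
  miss <- setdiff(need, names(gold))
  if (length(miss)) {
    stop("gold table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"population" %in% names(gold)) gold$population <- "NA"
  gold
}

#' Read NGS genotypes from a VCF, restricted to ARS-exon SNPs
#'
#' Keeps biallelic SNP records whose genomic positions fall inside the
#' configured ARS exons of any locus in the exon map; positions are
#' translated to 1-based CDS coordinates and, on `-` strand loci, REF/ALT
#' bases are reverse-complemented into CDS orientation. Skipped-record
#' counts are reported via `message()`.
#'
#' @param path VCF (v4.x) path; a GT FORMAT field is required.
#' @param exon_map output of [read_exon_map()].
#' @return Long tibble: `sample_id`, `locus`, `site` (CDS), `ref`, `alt`,
#'   `ngs1`, `ngs2` (single bases, `NA` for missing calls).
#' @export
read_vcf_ars_sites <- function(path, exon_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty VCF: ", path, call. = FALSE)
  fmt <- vcf@gt[, 1]
  if (!all(grepl("GT", fmt))) stop("VCF lacks GT format field", call. = FALSE)
  pos <- as.integer(fix$POS)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES
  gt <- vcfR::extract.gt(vcf, element = "GT")
  out <- list()
  n_in_exon <- 0L
  for (locus_id in names(exon_map)) {
    spec <- exon_map[[locus_id]]
    chrom_ok <- if (is.na(attr(spec, "chrom"))) TRUE
                else fix$CHROM == attr(spec, "chrom")
    cds <- genomic_to_cds(spec, pos)
    keep <- which(!is.na(cds) & chrom_ok & snp)
    n_in_exon <- n_in_exon + sum(!is.na(cds) & chrom_ok)
    if (length(keep) == 0L) next
    ref <- fix$REF[keep]; alt <- fix$ALT[keep]
    if (spec$strand == "-") { ref <- rev_comp(ref); alt <- rev_comp(alt) }
    g <- gt[keep, , drop = FALSE]
    samples <- colnames(g)
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    decode <- function(code, ref, alt) {
      dplyr::case_when(code == "0" ~ ref, code == "1" ~ alt,
                       TRUE ~ NA_character_)
    }
    refm <- matrix(rep(ref, length(samples)), ncol = length(samples))
    altm <- matrix(rep(alt, length(samples)), ncol = length(samples))
    out[[locus_id]] <- tibble::tibble(
      sample_id = rep(samples, each = length(keep)),
      locus = locus_id,
      site = rep(cds[keep], length(samples)),
      ref = rep(ref, length(samples)),
      alt = rep(alt, length(samples)),
      ngs1 = decode(as.vector(a1), as.vector(refm), as.vector(altm)),
      ngs2 = decode(as.vector(a2), as.vector(refm), as.vector(altm)))
  }
  n_skip <- nrow(fix) - n_in_exon
  message(sum(snp), "/", nrow(fix), " records are biallelic SNPs; ",
          n_skip, " records outside configured ARS exons skipped")
  if (length(out) == 0L) stop("no ARS-exon SNPs found in VCF", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Read a per-base depth table
#'
#' Tab-separated with columns `sample_id`, `chrom`, `pos` (genomic,
#' 1-based by default) and `depth`; positions are translated to CDS sites of
#' the loci in the exon map, rows outside all exons are dropped.
#'
#' @param path TSV file path.
#' @param exon_map output of [read_exon_map()].
#' @param zero_based set `TRUE` if positions are 0-based (BED-style starts).
#' @return Tibble: `sample_id`, `locus`, `site`, `depth`.
#' @export
read_depth_table <- function(path, exon_map, zero_based = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", chrom = "c", pos = "i", depth = "i"), progress = FALSE)
  if (zero_based) tab$pos <- tab$pos + 1L
  out <- list()
  for (locus_id in names(exon_map)) {
    spec <- exon_map[[locus_id]]
    chrom_ok <- if (is.na(attr(spec, "chrom"))) TRUE
                else tab$chrom == attr(spec, "chrom")
    cds <- genomic_to_cds(spec, tab$pos)
    keep <- !is.na(cds) & chrom_ok
    if (!any(keep)) next
    out[[locus_id]] <- tibble::tibble(
      sample_id = tab$sample_id[keep], locus = locus_id,
      site = cds[keep], depth = tab$depth[keep])
  }
  if (length(out) == 0L) stop("no depth records inside ARS exons", call. = FALSE)
  dplyr::bind_rows(out)
}
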