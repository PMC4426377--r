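# HLA allele nomenclature, ARS-exon catalog lookup, consensus sequences and
# CDS <-> genomic coordinate mapping.
#
# All per-site analysis runs in 1-based CDS coordinates over the concatenated
# ARS exons in coding orientation; VCF positions are translated on ingest.
# Per-position base sets ("A", or "A/T" for ambiguity) are encoded as strings
# of "/"-joined, alphabetically sorted bases.

BASES <- c("A", "C", "G", "T")

#' Encode a set of bases as a canonical base-set string
#'
#' @param bases character vector of bases in `A/C/G/T`.
#' @return A single string, e.g. `"A"` or `"A/T"` (sorted, unique).
#' @keywords internal
base_set <- function(bases) {
  paste(sort(unique(bases)), collapse = "/")
}

#' Decode a base-set string into its bases
#' @param x a base-set string such as `"A/T"`.
#' @return Character vector of bases.
#' @keywords internal
base_set_members <- function(x) {
  strsplit(x, "/", fixed = TRUE)[[1]]
}

rev_comp <- function(bases) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[bases])
}

#' Parse an HLA allele name
#'
#' Allele names consist of a locus designator, `*`, and 1-4 numeric fields
#' separated by colons (serotype group, nonsynonymous, synonymous, noncoding),
#' e.g. `B*35:03`. Expression-suffix letters (N, L, S, C, A, Q) are not part of
#' this data model and are rejected.
#'
#' @param raw allele name string.
#' @return A list with `locus`, `fields` (integer vector of length 1-4) and
#'   `raw` (the canonical reformatted name).
#' @export
#' @examples
#' parse_allele_name("B*35:03")
parse_allele_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  x <- trimws(raw)
  if (!grepl("*", x, fixed = TRUE)) {
    stop("malformed allele name (no '*'): '", raw, "'", call. = FALSE)
  }
  parts <- strsplit(x, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    stop("malformed allele name: '", raw, "'", call. = FALSE)
  }
  locus <- parts[1]
  if (grepl("^[0-9]+(:[0-9]+){0,3}[A-Za-z]$", parts[2])) {
    stop("allele name with expression suffix not supported: '", raw, "'",
         call. = FALSE)
  }
  if (!grepl("^[0-9]+(:[0-9]+){0,3}$", parts[2])) {
    stop("malformed allele fields in '", raw, "': '", parts[2], "'",
         call. = FALSE)
  }
  fields <- as.integer(strsplit(parts[2], ":", fixed = TRUE)[[1]])
  structure(
    list(locus = locus, fields = fields,
         raw = format_allele_name(locus, fields)),
    class = "hla_allele_name"
  )
}

#' Format an HLA allele name from its parts
#' @param locus locus designator.
#' @param fields integer vector of 1-4 numeric fields.
#' @return Canonical allele-name string with zero-padded two-digit fields.
#' @export
format_allele_name <- function(locus, fields) {
  paste0(locus, "*", paste(sprintf("%02d", fields), collapse = ":"))
}

#' Parse a possibly ambiguous allele call
#'
#' Typing ambiguity is reported as a `/`-separated list of candidate allele
#' names, e.g. `"B*35:02/B*35:03/B*35:04"`. All candidates must belong to one
#' locus.
#'
#' @param raw call string.
#' @return List with `locus` and `candidates` (list of parsed allele names).
#' @export
parse_allele_call <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  toks <- strsplit(trimws(raw), "/", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty allele call", call. = FALSE)
  cands <- lapply(toks, parse_allele_name)
  loci <- unique(vapply(cands, `[[`, "", "locus"))
  if (length(loci) != 1L) {
    stop("mixed loci in one allele call: '", raw, "' (",
         paste(loci, collapse = ", "), ")", call. = FALSE)
  }
  list(locus = loci, candidates = cands)
}

#' Build an allele catalog from names and ARS coding sequences
#'
#' @param names character vector of full allele names (FASTA headers).
#' @param seqs character vector of uppercase ARS coding sequences, one per
#'   name; all sequences of one locus must share a common length.
#' @return A tibble with columns `name`, `locus`, `key` (colon-joined integer
#'   fields) and `seq`, of class `allele_catalog`.
#' @export
allele_catalog <- function(names, seqs) {
  stopifnot(length(names) == length(seqs))
  parsed <- lapply(names, parse_allele_name)
  cat <- tibble::tibble(
    name  = vapply(parsed, `[[`, "", "raw"),
    locus = vapply(parsed, `[[`, "", "locus"),
    key   = vapply(parsed, function(p) paste(p$fields, collapse = ":"), ""),
    seq   = unname(toupper(seqs))
  )
  bad <- !grepl("^[ACGT]+$", cat$seq)
  if (any(bad)) {
    stop("catalog sequences with non-ACGT characters: ",
         paste(utils::head(cat$name[bad], 3), collapse = ", "), call. = FALSE)
  }
  lens <- tapply(nchar(cat$seq), cat$locus, function(x) length(unique(x)))
  if (any(lens != 1L)) {
    stop("catalog sequences of unequal length within a locus", call. = FALSE)
  }
  class(cat) <- c("allele_catalog", class(cat))
  cat
}

# All catalog entries matching one (possibly lower-resolution) allele name:
# a k-field query matches every entry whose first k fields agree.
catalog_matches <- function(catalog, allele) {
  sub <- catalog[catalog$locus == allele$locus, , drop = FALSE]
  if (nrow(sub) == 0L) return(sub)
  q <- allele$fields
  keep <- vapply(strsplit(sub$key, ":", fixed = TRUE), function(f) {
    length(f) >= length(q) && all(as.integer(f[seq_along(q)]) == q)
  }, logical(1))
  sub[keep, , drop = FALSE]
}

#' Expand an allele call into a per-position consensus sequence
#'
#' Every candidate name contributes all catalog sequences matching it (a
#' lower-resolution name matches all higher-resolution entries that share its
#' leading fields). The consensus holds, at each CDS position, the set of
#' bases observed across the contributing sequences: unanimous positions are
#' singletons, ambiguous positions carry all observed bases (e.g. `"A/T"`).
#'
#' @param call result of [parse_allele_call()].
#' @param catalog an [allele_catalog()].
#' @return Character vector of base-set strings, length `cds_length`.
#' @export
expand_call_to_consensus <- function(call, catalog) {
  seq_sets <- lapply(call$candidates, function(a) catalog_matches(catalog, a))
  missing <- vapply(seq_sets, nrow, 0L) == 0L
  if (any(missing)) {
    miss <- vapply(call$candidates[missing], `[[`, "", "raw")
    stop("allele name(s) not found in catalog: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  seqs <- unique(unlist(lapply(seq_sets, `[[`, "seq")))
  if (length(seqs) == 1L) {
    return(strsplit(seqs, "", fixed = TRUE)[[1]])
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  apply(mat, 2, base_set)
}

#' Deconstruct two consensus sequences into per-site gold genotypes
#'
#' @param copy1,copy2 consensus sequences (base-set string vectors) for the
#'   two chromosome copies, same length.
#' @param sites integer vector of 1-based CDS positions.
#' @return Tibble with columns `site`, `gold1`, `gold2` (base-set strings; the
#'   pair is unordered by convention but copy order is preserved).
#' @export
deconstruct_genotypes <- function(copy1, copy2, sites) {
  stopifnot(length(copy1) == length(copy2))
  if (any(sites < 1L | sites > length(copy1))) {
    stop("site outside [1, cds_length]", call. = FALSE)
  }
  tibble::tibble(site = as.integer(sites),
                 gold1 = copy1[sites], gold2 = copy2[sites])
}

#' Construct a locus specification
#'
#' @param locus_id short locus designator (e.g. `"A"`, `"DQB1"`).
#' @param exons data frame with columns `label`, `start`, `end` (1-based
#'   inclusive genomic coordinates), in coding order.
#' @param strand `"+"` or `"-"`.
#' @param class `"I"` (ARS = exons 2+3, CDS length 546) or `"II"` (exon 2,
#'   270).
#' @param reference_ars_seq uppercase index (reference genome) sequence over
#'   the concatenated ARS exons, in coding orientation.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(locus_id, exons, strand = "+", class = "I",
                       reference_ars_seq = NULL) {
  stopifnot(strand %in% c("+", "-"), class %in% c("I", "II"))
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)),
            all(exons$end >= exons$start))
  lens <- exons$end - exons$start + 1L
  cds_length <- sum(lens)
  if (!is.null(reference_ars_seq)) {
    reference_ars_seq <- toupper(reference_ars_seq)
    if (nchar(reference_ars_seq) != cds_length) {
      stop("reference_ars_seq length (", nchar(reference_ars_seq),
           ") != sum of exon lengths (", cds_length, ")", call. = FALSE)
    }
    if (!grepl("^[ACGT]+$", reference_ars_seq)) {
      stop("reference_ars_seq contains non-ACGT characters", call. = FALSE)
    }
  }
  structure(
    list(locus_id = locus_id, exons = exons, strand = strand, class = class,
         cds_length = cds_length, reference_ars_seq = reference_ars_seq),
    class = "locus_spec"
  )
}

#' Map a CDS position to its genomic coordinate
#'
#' CDS positions run 1..cds_length over the concatenated ARS exons in coding
#' orientation. On `-` strand loci CDS position 1 maps to the highest genomic
#' coordinate of the first coding exon.
#'
#' @param locus a [locus_spec()].
#' @param cds_pos integer vector of 1-based CDS positions.
#' @return Integer vector of 1-based genomic positions.
#' @export
cds_to_genomic <- function(locus, cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(cds_pos < 1L | cds_pos > locus$cds_length)) {
    stop("CDS position out of range 1..", locus$cds_length, call. = FALSE)
  }
  lens <- locus$exons$end - locus$exons$start + 1L
  cum_before <- cumsum(c(0L, lens))[seq_along(lens)]
  ex <- findInterval(cds_pos - 1L, cumsum(c(0L, lens)),
                     rightmost.closed = FALSE)
  off <- cds_pos - cum_before[ex] - 1L
  if (locus$strand == "+") {
    locus$exons$start[ex] + off
  } else {
    locus$exons$end[ex] - off
  }
}

#' Map a genomic coordinate to its CDS position
#'
#' Inverse of [cds_to_genomic()]; positions outside all ARS exons return `NA`.
#'
#' @inheritParams cds_to_genomic
#' @param genomic_pos integer vector of 1-based genomic positions.
#' @return Integer vector of CDS positions (`NA` outside the exons).
#' @export
genomic_to_cds <- function(locus, genomic_pos) {
  genomic_pos <- as.integer(genomic_pos)
  lens <- locus$exons$end - locus$exons$start + 1L
  cum_before <- cumsum(c(0L, lens))[seq_along(lens)]
  out <- rep(NA_integer_, length(genomic_pos))
  for (i in seq_len(nrow(locus$exons))) {
    s <- locus$exons$start[i]; e <- locus$exons$end[i]
    hit <- !is.na(genomic_pos) & genomic_pos >= s & genomic_pos <= e
    if (!any(hit)) next
    out[hit] <- if (locus$strand == "+") {
      cum_before[i] + genomic_pos[hit] - s + 1L
    } else {
      cum_before[i] + e - genomic_pos[hit] + 1L
    }
  }
  out
}
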