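# The mapping-bias window test: 51-bp windows centred on each SNP from every
# chromosome copy in the sample, split by REF/ALT central allele, mismatch
# counts against the index (reference genome) sequence excluding the central
# site, and one-tailed rank-sum comparisons between groups.

#' Build flanking windows around a SNP from per-copy sequences
#'
#' One window per chromosome copy, spanning `site - half_width` to
#' `site + half_width` and truncated at the CDS boundaries (no padding). The
#' central allele class is REF when the copy carries `ref_base` at `site`,
#' ALT otherwise; copies with residual ambiguity at the central site are
#' excluded from both groups (`central_class = NA`).
#'
#' @param sequences list of consensus sequences (base-set string vectors of
#'   common length), one per chromosome copy.
#' @param site central CDS position.
#' @param ref_base REF base at `site`.
#' @param half_width flank length on each side (default 25, i.e. 51-bp
#'   windows).
#' @param source optional tibble with one row per copy (e.g. `sample_id`,
#'   `copy`) carried through to the output.
#' @return Tibble with `central_class`, `win_start`, `win_end`,
#'   `central_offset` (position of the SNP within the window) and
#'   `window_seq` (list column of base-set vectors), plus `source` columns.
#' @export
build_windows <- function(sequences, site, ref_base, half_width = 25,
                          source = NULL) {
  L <- length(sequences[[1]])
  if (site < 1L || site > L) stop("site out of range 1..", L, call. = FALSE)
  ws <- max(1L, site - half_width)
  we <- min(L, site + half_width)
  centre <- vapply(sequences, function(s) s[site], "")
  cls <- ifelse(grepl("/", centre, fixed = TRUE), NA_character_,
                ifelse(centre == ref_base, "REF", "ALT"))
  out <- tibble::tibble(
    site = as.integer(site),
    central_class = cls,
    win_start = ws, win_end = we,
    central_offset = site - ws + 1L,
    window_seq = lapply(sequences, function(s) s[ws:we])
  )
  if (!is.null(source)) out <- dplyr::bind_cols(source, out)
  out
}

#' Count window mismatches against the index sequence
#'
#' Hamming distance between a window and the corresponding index slice,
#' excluding any mismatch at the central SNP. A residually ambiguous window
#' position counts as a match when the index base belongs to the ambiguity
#' set, else as one mismatch.
#'
#' @param window_seq base-set string vector (one window).
#' @param index_window matching slice of the index sequence (single bases).
#' @param central_offset position of the central SNP within the window.
#' @return Integer mismatch count.
#' @export
count_window_mismatches <- function(window_seq, index_window, central_offset) {
  if (length(window_seq) != length(index_window)) {
    stop("window and index slice lengths differ", call. = FALSE)
  }
  mm <- !mapply(function(w, r) r %in% base_set_members(w),
                window_seq, index_window)
  mm[central_offset] <- FALSE
  sum(mm)
}

#' Vectorised window mismatch counts for many copies and sites
#'
#' Equivalent to [build_windows()] + [count_window_mismatches()] over every
#' copy and every site, via cumulative sums over a per-position mismatch
#' matrix. Used by the pipeline for speed; tested against the per-window
#' counter.
#'
#' @param seq_mat character matrix (copies x CDS positions) of base-set
#'   strings.
#' @param index_seq index sequence as a character vector of single bases.
#' @param sites integer vector of central CDS positions.
#' @param half_width flank length (default 25).
#' @param include_central logical: count a central-site mismatch too (the
#'   read-retention model does; the analysis statistic does not).
#' @return Integer matrix (copies x sites) of mismatch counts.
#' @export
window_mismatch_counts <- function(seq_mat, index_seq, sites,
                                   half_width = 25, include_central = FALSE) {
  L <- ncol(seq_mat)
  stopifnot(length(index_seq) == L)
  amb <- grepl("/", seq_mat, fixed = TRUE)
  mm <- seq_mat != rep(index_seq, each = nrow(seq_mat))
  if (any(amb)) {
    idx <- which(amb)
    ref_here <- rep(index_seq, each = nrow(seq_mat))[idx]
    mm[idx] <- !mapply(function(w, r) r %in% base_set_members(w),
                       seq_mat[idx], ref_here)
  }
  cs <- cbind(0L, t(apply(mm, 1L, cumsum)))
  out <- matrix(0L, nrow(seq_mat), length(sites))
  for (j in seq_along(sites)) {
    s <- sites[j]
    ws <- max(1L, s - half_width); we <- min(L, s + half_width)
    tot <- cs[, we + 1L] - cs[, ws]
    if (!include_central) tot <- tot - mm[, s]
    out[, j] <- as.integer(tot)
  }
  out
}

#' One-tailed Mann-Whitney rank-sum test
#'
#' Tests the alternative that `group_a` is stochastically greater than
#' `group_b`. Uses exact enumeration over all group assignments when
#' `choose(na + nb, na)` is small enough (covering ties correctly), and the
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_limit maximum number of assignments enumerated exactly.
#' @return One-tailed p-value.
#' @export
mannwhitney_one_tailed <- function(group_a, group_b, exact_limit = 2e5) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("empty group", call. = FALSE)
  comb <- c(group_a, group_b)
  n <- na + nb
  rk <- rank(comb)  # midranks
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (choose(n, na) <= exact_limit) {
    idx <- utils::combn(n, na)
    u_all <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
    return(mean(u_all >= u_obs - 1e-9))
  }
  na_d <- as.numeric(na); nb_d <- as.numeric(nb); n_d <- as.numeric(n)
  ties <- as.numeric(table(comb))
  tie_term <- sum(ties^3 - ties) / (n_d * (n_d - 1))
  mu <- na_d * nb_d / 2
  sigma2 <- na_d * nb_d / 12 * (n_d + 1 - tie_term)
  if (sigma2 <= 0) return(1)  # all values tied: no evidence of a shift
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Mapping-bias mechanism report
#'
#' Groups window observations by site classification and central-allele class,
#' reports group means and sizes, and a one-tailed rank-sum p-value for the
#' alternative that ALT windows carry more mismatches than REF windows within
#' each site class. Classes missing either group are omitted with a warning.
#'
#' @param windows tibble with columns `site_class`, `central_class` and
#'   `mismatch_count` (rows with `NA` central class are dropped).
#' @param classes site classes to report, in order.
#' @return List with `groups` (tibble: site_class, central_class, n, mean)
#'   and `tests` (tibble: site_class, n_ref, n_alt, mean_ref, mean_alt, p).
#' @export
bias_mechanism_report <- function(windows,
                                  classes = c("overestimated",
                                              "well_estimated",
                                              "underestimated")) {
  w <- windows[!is.na(windows$central_class) &
                 windows$site_class %in% classes, , drop = FALSE]
  groups <- dplyr::summarise(
    dplyr::group_by(w, site_class, central_class),
    n = dplyr::n(), mean = mean(mismatch_count), .groups = "drop")
  tests <- list()
  for (cl in classes) {
    a <- w$mismatch_count[w$site_class == cl & w$central_class == "ALT"]
    b <- w$mismatch_count[w$site_class == cl & w$central_class == "REF"]
    if (length(a) == 0L || length(b) == 0L) {
      if (any(w$site_class == cl) || cl %in% windows$site_class) {
        warning("site class '", cl, "' lacks REF or ALT windows; omitted",
                call. = FALSE)
      }
      next
    }
    tests[[cl]] <- tibble::tibble(
      site_class = cl, n_ref = length(b), n_alt = length(a),
      mean_ref = mean(b), mean_alt = mean(a),
      p = mannwhitney_one_tailed(a, b))
  }
  list(groups = groups, tests = dplyr::bind_rows(tests))
}
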