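test_that("windows truncate at CDS edges and classify the central allele", {
  L <- 100
  idx <- rep("A", L)
  s1 <- rep("A", L); s1[50] <- "T"
  s2 <- rep("A", L); s2[50] <- "A/T"  # residual central ambiguity
  w <- build_windows(list(idx, s1, s2), site = 50, ref_base = "A")
  expect_equal(w$central_class, c("REF", "ALT", NA))
  expect_equal(lengths(w$window_seq), rep(51L, 3))
  expect_equal(w$central_offset, rep(26L, 3))

  w1 <- build_windows(list(s1), site = 1, ref_base = "A")
  expect_equal(lengths(w1$window_seq), 26L)  # no upstream flank
  w2 <- build_windows(list(s1), site = 99, ref_base = "A")
  expect_equal(lengths(w2$window_seq), 27L)
  expect_error(build_windows(list(s1), site = 0, ref_base = "A"),
               "out of range")
})

test_that("one window per chromosome copy: 2 per diploid individual", {
  L <- 80
  copies <- replicate(14, rep("C", L), simplify = FALSE)  # 7 individuals
  w <- build_windows(copies, site = 40, ref_base = "C")
  expect_equal(nrow(w), 14)
})

test_that("central mismatch is excluded from the window count", {
  idx <- strsplit("ACGTACGTACG", "")[[1]]
  win <- idx
  expect_equal(count_window_mismatches(win, idx, 6), 0)
  win[6] <- "T"  # only the central site differs
  expect_equal(count_window_mismatches(win, idx, 6), 0)
  win[c(2, 9)] <- c("G", "C")  # two flanking differences
  expect_equal(count_window_mismatches(win, idx, 6), 2)
  # ambiguity: match when the index base is in the set
  win2 <- idx; win2[3] <- "G/T"; win2[4] <- "A/C"
  expect_equal(count_window_mismatches(win2, idx, 6), 1)
  expect_error(count_window_mismatches(win[1:5], idx, 3), "lengths differ")
})

test_that("vectorised window counts equal the brute-force Hamming oracle", {
  set.seed(17)
  L <- 60
  hw <- 10
  for (rep in 1:25) {
    n_copy <- 8
    mat <- matrix(sample(BASES_T, n_copy * L, replace = TRUE), n_copy, L)
    idx <- sample(BASES_T, L, replace = TRUE)
    sites <- sort(sample(L, 5))
    fast <- window_mismatch_counts(mat, idx, sites, half_width = hw)
    for (j in seq_along(sites)) {
      s <- sites[j]
      ws <- max(1, s - hw); we <- min(L, s + hw)
      for (i in seq_len(n_copy)) {
        slow <- sum(mat[i, ws:we] != idx[ws:we]) -
          as.integer(mat[i, s] != idx[s])
        expect_equal(fast[i, j], slow)
      }
    }
  }
})

test_that("rank-sum exact p equals enumeration and handles ties", {
  # full separation of 3 vs 3: exactly 1 of choose(6,3)=20 assignments
  expect_equal(mannwhitney_one_tailed(c(5, 6, 7), c(1, 2, 3)), 1 / 20)
  # identical samples carry no evidence of a shift
  expect_gte(mannwhitney_one_tailed(c(1, 2, 3), c(1, 2, 3)), 0.5)

  # oracle: enumeration counting pairwise wins (independent of midranks)
  u_enum_p <- function(a, b) {
    comb <- c(a, b); na <- length(a)
    u_of <- function(ia) {
      av <- comb[ia]; bv <- comb[-ia]
      sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
    }
    u_obs <- u_of(seq_len(na))
    ids <- utils::combn(length(comb), na)
    mean(apply(ids, 2, u_of) >= u_obs - 1e-9)
  }
  set.seed(9)
  for (i in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(0:5, na, replace = TRUE)  # heavy ties
    b <- sample(0:5, nb, replace = TRUE)
    expect_equal(mannwhitney_one_tailed(a, b), u_enum_p(a, b),
                 tolerance = 1e-12)
  }
  # tie-free data: agrees with the Wilcoxon distribution in wilcox.test
  for (i in 1:10) {
    x <- sample(1000, 16)
    a <- x[1:8]; b <- x[9:16]
    wt <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(mannwhitney_one_tailed(a, b), wt$p.value, tolerance = 1e-12)
  }
  expect_error(mannwhitney_one_tailed(numeric(0), 1), "empty")
})

test_that("normal approximation tracks wilcox.test on large tied samples", {
  set.seed(31)
  a <- rpois(300, 4); b <- rpois(300, 3.5)
  p_pkg <- mannwhitney_one_tailed(a, b)
  p_ref <- stats::wilcox.test(a, b, alternative = "greater",
                              exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-9)

  # strongly shifted normals underflow far past any reporting floor
  a <- stats::rnorm(500, 2); b <- stats::rnorm(500, 0)
  expect_lt(mannwhitney_one_tailed(a, b), 1e-16)

  # group sizes whose product exceeds .Machine$integer.max
  a <- rep(c(1, 2, 3), 20000); b <- rep(c(1, 2, 3), 21000)
  expect_equal(mannwhitney_one_tailed(a, b), 0.5, tolerance = 1e-3)
})

test_that("bias report recovers a deterministic flank differential", {
  # one ALT haplotype carrying exactly 3 extra flanking variants
  L <- 120; s <- 60
  idx <- rep("A", L)
  ref_hap <- idx
  alt_hap <- idx; alt_hap[s] <- "T"; alt_hap[c(s - 5, s + 4, s + 9)] <- "C"
  copies <- c(replicate(6, ref_hap, simplify = FALSE),
              replicate(4, alt_hap, simplify = FALSE))
  mat <- do.call(rbind, copies)
  counts <- window_mismatch_counts(mat, idx, s)
  w <- tibble::tibble(site_class = "overestimated",
                      central_class = ifelse(mat[, s] == "A", "REF", "ALT"),
                      mismatch_count = as.vector(counts))
  rep <- bias_mechanism_report(w)
  expect_equal(rep$tests$mean_alt - rep$tests$mean_ref, 3)
  expect_equal(rep$tests$n_ref, 6)
  expect_equal(rep$tests$n_alt, 4)
  expect_lt(rep$tests$p, 0.05)  # exact p = 1/C(10,4)
})

test_that("classes lacking a REF or ALT group are omitted with a warning", {
  w <- tibble::tibble(
    site_class = c("overestimated", "overestimated", "well_estimated"),
    central_class = c("REF", "ALT", "REF"),
    mismatch_count = c(1, 4, 0))
  expect_warning(rep <- bias_mechanism_report(w), "well_estimated")
  expect_equal(rep$tests$site_class, "overestimated")
})
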