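test_that("REF frequency counts alleles with fractional residual ambiguity", {
  expect_equal(ref_allele_frequency(c("A", "A", "T"), c("A", "T", "T"), "A"),
               0.5)
  expect_equal(ref_allele_frequency(rep("G", 5), rep("G", 5), "G"), 1.0)
  # residual ambiguous set containing REF counts 0.5
  expect_equal(ref_allele_frequency(c("A/T", "A"), c("C", "A"), "A"),
               (0.5 + 0 + 1 + 1) / 4)
  # missing genotypes excluded from the denominator
  expect_equal(ref_allele_frequency(c("A", NA), c("T", NA), "A"), 0.5)
  expect_error(ref_allele_frequency(NA_character_, NA_character_, "A"),
               "non-missing")
})

test_that("FE and MAE follow their definitions", {
  expect_equal(frequency_error(0.7, 0.5), 0.2)
  expect_equal(frequency_error(0.5, 0.5), 0)
  expect_equal(mae(c(0.1, -0.3, 0.2)), 0.2)
  expect_equal(mae(0), 0)
  expect_error(mae(numeric(0)), "empty")
  # triangle inequality
  set.seed(5)
  for (i in 1:20) {
    fe <- stats::runif(10, -1, 1)
    expect_gte(mae(fe), abs(mean(fe)))
  }
})

test_that("site classification partitions FE values", {
  expect_equal(classify_site(0.15), "overestimated")
  expect_equal(classify_site(-0.2), "underestimated")
  expect_equal(classify_site(0.005), "well_estimated")
  expect_equal(classify_site(0.05), "intermediate")
  # boundary values are intermediate, not over/under/well
  expect_equal(classify_site(c(0.1, -0.1, 0.01, -0.01)),
               rep("intermediate", 4))
  fe <- seq(-1, 1, by = 0.001)
  cls <- classify_site(fe)
  expect_true(all(cls %in% c("overestimated", "underestimated",
                             "well_estimated", "intermediate")))
  expect_false(any(is.na(cls)))
})

test_that("unreliable sites need |FE| > threshold in two or more populations", {
  fe_tab <- tibble::tibble(
    site = rep(1:3, each = 12),
    population = rep(sprintf("P%02d", 1:12), 3),
    fe = c(c(0.15, rep(0, 11)),           # large in 1 pop only
           c(0.12, -0.2, rep(0, 10)),     # large in 2 pops, mixed sign
           rep(0.05, 12)))                # never large
  fl <- unreliable_sites(fe_tab)
  expect_equal(fl$site, 2L)
  expect_equal(fl$n_pops_large, 2L)
  expect_equal(nrow(unreliable_sites(fe_tab, min_pops = 1)), 2)
})

test_that("direction test matches exact binomial enumeration", {
  expect_equal(direction_test(5, 5), 1.0)
  expect_equal(direction_test(3, 11), direction_test(11, 3))
  # oracle: sum of probabilities of outcomes no more likely than observed
  enum_p <- function(k, n) {
    d <- stats::dbinom(0:n, n, 0.5)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
  }
  for (n in 1:20) for (k in 0:n) {
    expect_equal(direction_test(k, n - k), enum_p(k, n), tolerance = 1e-12,
                 info = paste(k, n))
  }
  expect_error(direction_test(0, 0), "at least one")
})

test_that("heterozygosity is 2p(1-p)", {
  expect_equal(heterozygosity(0.5), 0.5)
  expect_equal(heterozygosity(0), 0)
  expect_equal(heterozygosity(0.1), 0.18)
  expect_error(heterozygosity(1.2))
})

test_that("Pearson correlation matches the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_with_p(x, -x)$r, -1.0)

  y <- c(2.3, 1.1, 4.8, 3.9, 2.5)
  ct <- pearson_with_p(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(ct$r, r_direct, tolerance = 1e-12)
  expect_equal(ct$p, 2 * stats::pt(-abs(tstat), df = 3), tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), y), "constant")
})

test_that("heterozygosity filter report splits flagged and retained sites", {
  gf <- tibble::tibble(site = 1:4, f_gold = c(0.5, 0.5, 0.9, 0.8))
  fl <- tibble::tibble(site = 1:2)
  rep <- heterozygosity_filter_report(gf, fl)
  expect_equal(rep$mean_excluded, 0.5)
  expect_length(rep$retained, 2)
  expect_gt(rep$mean_excluded, rep$mean_retained)

  none <- heterozygosity_filter_report(gf, fl[0, , drop = FALSE])
  expect_length(none$excluded, 0)
})

test_that("frequency table pools populations into a global stratum", {
  res <- tibble::tibble(
    sample_id = sprintf("S%d", 1:4),
    population = c("P1", "P1", "P2", "P2"),
    site = 1L, ref = "A",
    gold1 = c("A", "A", "T", "T"), gold2 = c("A", "T", "T", "T"),
    ngs1 = c("A", "A", "A", "T"), ngs2 = c("A", "A", "T", "T"))
  ft <- frequency_table(res)
  glob <- ft[ft$population == "global", ]
  expect_equal(glob$f_gold, 3 / 8)
  expect_equal(glob$f_ngs, 5 / 8)
  expect_equal(glob$fe, 0.25)
  p1 <- ft[ft$population == "P1", ]
  expect_equal(p1$f_gold, 3 / 4)
  # frequencies of REF and ALT sum to one in both datasets
  expect_true(all(ft$f_ngs >= 0 & ft$f_ngs <= 1))
})
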