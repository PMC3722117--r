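test_that("signed-rank p-values on all-positive differences match enumeration", {
  # d = 1..5 all positive: W- = 0, exact two-sided p = 2/32
  r5 <- wilcoxon_signed_rank(6:10, 5:1 * 0 + 5)
  expect_equal(r5$p_two_sided, wilcoxon_enum_oracle(6:10, rep(5, 5)))
  d <- 1:5
  r <- wilcoxon_signed_rank(d + 10, rep(10, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 2 / 32)
  expect_false(r$significant)  # 0.0625 > 0.05
  # n = 6 all positive: p = 2/64 = 0.03125, significant
  r6 <- wilcoxon_signed_rank(1:6 + 10, rep(10, 6))
  expect_equal(r6$p_two_sided, 2 / 64)
  expect_true(r6$significant)
})

test_that("degenerate all-zero differences give p = 1 with a flag", {
  x <- c(3.2, 4.1, 7.7)
  r <- wilcoxon_signed_rank(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$n_effective, 0L)
})

test_that("exact p matches full 2^n enumeration incl. ties (n <= 12)", {
  set.seed(91)
  for (rep in 1:50) {
    n <- sample(1:12, 1)
    # half-unit grid induces ties in |d| and some zero differences
    x <- round(rnorm(n, 0, 2) * 2) / 2
    y <- round(rnorm(n, 0, 2) * 2) / 2
    if (all(x == y)) x[1] <- x[1] + 0.5
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_two_sided, wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when that is exact", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties, no zeros
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("p is shift invariant and symmetric under swapping the samples", {
  set.seed(111)
  x <- rnorm(15); y <- rnorm(15)
  p0 <- wilcoxon_signed_rank(x, y)$p_two_sided
  expect_equal(wilcoxon_signed_rank(x + 3.3, y + 3.3)$p_two_sided, p0)
  expect_equal(wilcoxon_signed_rank(y, x)$p_two_sided, p0)
})

test_that("type-I error is calibrated near the nominal 5% level", {
  set.seed(121)
  n_sim <- 2000
  rejections <- 0L
  for (s in seq_len(n_sim)) {
    x <- rnorm(20); y <- rnorm(20)  # paired null: same distribution
    if (wilcoxon_signed_rank(x, y)$significant) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("normal approximation is close to exact around the switch point", {
  set.seed(131)
  for (rep in 1:10) {
    x <- rnorm(24); y <- rnorm(24)
    p_exact <- wilcoxon_signed_rank(x, y, exact_max_n = 25)$p_two_sided
    p_approx <- wilcoxon_signed_rank(x, y, exact_max_n = 0)$p_two_sided
    expect_lt(abs(p_exact - p_approx), 0.015)
  }
})

test_that("median follows the even-n midpoint definition", {
  expect_equal(cohort_median(43.7), 43.7)
  expect_equal(cohort_median(c(1, 2, 3, 4)), 2.5)
  set.seed(141)
  v <- runif(1000)
  s <- sort(v)
  expect_equal(cohort_median(v), (s[500] + s[501]) / 2)
  expect_error(cohort_median(numeric(0)), "empty")
})

fake_records <- function(n, sites = NULL, btv_factor = 0.5, seed = 1) {
  set.seed(seed)
  if (is.null(sites))
    sites <- rep(c("lung", "oesophageal", "pelvic"), length.out = n)
  algs <- c("SUV38", "SUV42", "SUV47", "SUV50", "PERCIST")
  do.call(rbind, lapply(seq_len(n), function(i) {
    gtv <- runif(1, 20, 90)
    data.frame(patient_id = sprintf("P%02d", i), site = sites[i],
               suv_max = runif(1, 3, 18), algorithm = algs,
               gtv_ml = gtv, btv_ml = gtv * btv_factor,
               conformity_index_pct = 100 * btv_factor,
               btv_in_gtv_pct = 100, gtv_in_btv_pct = 100 * btv_factor,
               stringsAsFactors = FALSE)
  }))
}

test_that("cohort summary reproduces constructed medians and detects the
           volume deficit", {
  rec <- fake_records(20, btv_factor = 0.5)
  s <- summarize_cohort(rec)
  expect_equal(s$algorithm[1], "GTV")
  expect_setequal(s$algorithm[-1],
                  c("SUV38", "SUV42", "SUV47", "SUV50", "PERCIST"))
  # every BTV = GTV/2: median BTV = median GTV / 2, CI <= 50 everywhere
  expect_equal(s$cohort_median_ml[2], s$cohort_median_ml[1] / 2)
  expect_true(all(s$cohort_median_ci_pct[-1] <= 50))
  # paired Wilcoxon detects the systematic deficit for every algorithm
  expect_true(all(s$cohort_p_vs_gtv[-1] < 0.05))
  # subgroup medians use only that site's patients
  lung <- rec[rec$site == "lung" & rec$algorithm == "SUV38", ]
  expect_equal(s$lung_median_ml[1], cohort_median(lung$gtv_ml))
})

test_that("single-patient cohort and empty subgroups are handled", {
  rec <- fake_records(1, sites = "lung")
  s <- summarize_cohort(rec)
  expect_equal(s$cohort_median_ml[1], rec$gtv_ml[1])
  expect_true(all(is.na(s$oesophageal_median_ml)))
  expect_error(summarize_cohort(rec[0, ]), "nonempty")
})

test_that("even-sized subgroup median is the midpoint of the central pair", {
  rec <- fake_records(4, sites = rep("lung", 4))
  s <- summarize_cohort(rec)
  gtvs <- sort(unique(rec$gtv_ml))
  expect_equal(s$lung_median_ml[1], mean(gtvs[2:3]))
})

test_that("cohort CSV round trip preserves the records", {
  rec <- fake_records(5)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(rec, f)
  back <- read_cohort_csv(f)
  expect_equal(back$btv_ml, rec$btv_ml)
  expect_equal(back$algorithm, rec$algorithm)
  unlink(f)
})

test_that("the rendered cohort table has Table-2-style rows and blocks", {
  rec <- fake_records(12)
  s <- summarize_cohort(rec)
  lines <- capture.output(tbl <- format_cohort_table(s))
  expect_equal(length(tbl), 2 + 6)  # header + rule + GTV + 5 algorithms
  expect_match(tbl[1], "cohort")
  expect_match(tbl[1], "lung")
  expect_match(tbl[1], "oesophageal")
  expect_match(tbl[1], "pelvic")
  expect_match(tbl[3], "^GTV")
})
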