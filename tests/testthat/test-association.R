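test_that("driver group labels follow the fixed A,P,B,K order and partition cohorts", {
  expect_equal(assign_driver_group(TRUE, FALSE, FALSE, TRUE), "AK")
  expect_equal(assign_driver_group(FALSE, FALSE, FALSE, FALSE), "N")
  expect_equal(assign_driver_group(TRUE, TRUE, TRUE, TRUE), "APBK")
  set.seed(61)
  n <- 300
  g <- assign_driver_group(
    runif(n) < 0.7, runif(n) < 0.6, runif(n) < 0.1, runif(n) < 0.45
  )
  expect_equal(length(g), n)
  expect_equal(sum(table(g)), n) # labels partition the cohort
  expect_true(all(g %in% c(
    "N", "A", "P", "B", "K", "AP", "AB", "AK", "PB", "PK", "BK",
    "APB", "APK", "ABK", "PBK", "APBK"
  )))
})

make_matrix <- function(x, y, subtype = "MT-L") {
  data.frame(
    sample_id = as.character(seq_along(x)), subtype = subtype, stage = "II",
    PTEN.mutation_any = x, TP53.mutation_any = y
  )
}

test_that("Fisher co-occurrence p-values equal hypergeometric enumeration", {
  # worked example: table (3,1; 1,3) has two-sided p = 34/70
  x <- c(rep(TRUE, 4), rep(FALSE, 4))
  y <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 3))
  res <- test_cooccurrence(make_matrix(x, y), "PTEN.mutation_any", "TP53.mutation_any")
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-9)
  expect_equal(res$p_value, fisher_p_oracle(3, 1, 1, 3), tolerance = 1e-9)
  # perfectly separated table: minimal p for the margins, Haldane OR finite
  x2 <- rep(c(TRUE, FALSE), each = 10)
  res2 <- test_cooccurrence(make_matrix(x2, x2), "PTEN.mutation_any", "TP53.mutation_any")
  expect_equal(res2$p_value, fisher_p_oracle(10, 0, 0, 10), tolerance = 1e-9)
  expect_lt(res2$p_value, 0.005)
  expect_true(is.finite(res2$odds_ratio) && res2$odds_ratio > 1)
})

test_that("random 2x2 tables match the enumeration oracle (n <= 40)", {
  set.seed(67)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    x <- sample(c(TRUE, FALSE), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- test_cooccurrence(make_matrix(x, y), "PTEN.mutation_any", "TP53.mutation_any")
    a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
    expect_equal(res$p_value, fisher_p_oracle(a, b, c_, d), tolerance = 1e-7)
  }
})

test_that("odds ratios are transpose-invariant and label exclusivity correctly", {
  x <- c(rep(TRUE, 12), rep(FALSE, 18))
  y <- c(rep(TRUE, 2), rep(FALSE, 10), rep(TRUE, 14), rep(FALSE, 4))
  r_xy <- test_cooccurrence(make_matrix(x, y), "PTEN.mutation_any", "TP53.mutation_any")
  r_yx <- test_cooccurrence(make_matrix(y, x), "PTEN.mutation_any", "TP53.mutation_any")
  expect_equal(r_xy$odds_ratio, r_yx$odds_ratio)
  expect_equal(r_xy$p_value, r_yx$p_value)
  expect_lt(r_xy$odds_ratio, 1) # mutual exclusivity
  # degenerate margin -> untestable
  r_deg <- test_cooccurrence(
    make_matrix(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
    "PTEN.mutation_any", "TP53.mutation_any"
  )
  expect_true(r_deg$untestable)
  expect_true(is.na(r_deg$p_value))
  # stratum filtering
  m <- make_matrix(x, y, subtype = rep(c("MT-L", "MT-H"), 15))
  r_str <- test_cooccurrence(m, "PTEN.mutation_any", "TP53.mutation_any", stratum = "MT-L")
  expect_equal(sum(r_str$table), 15)
  expect_error(
    test_cooccurrence(m, "PTEN.mutation_any", "TP53.mutation_any", stratum = "nope"),
    "empty"
  )
})

test_that("co-occurrence tests are calibrated under independence", {
  set.seed(71)
  pvals <- replicate(200, {
    x <- runif(120) < 0.3
    y <- runif(120) < 0.4
    r <- test_cooccurrence(make_matrix(x, y), "PTEN.mutation_any", "TP53.mutation_any")
    r$p_value
  })
  pvals <- pvals[!is.na(pvals)]
  expect_lte(mean(pvals < 0.005), 0.015) # Fisher is conservative
})

test_that("allele-fraction normalization is elementwise division with validation", {
  expect_equal(normalize_af(0.3, 0.3), 1)
  expect_equal(normalize_af(0.2, 0.4), 0.5)
  set.seed(73)
  a <- runif(20, 0.05, 0.9)
  b <- runif(20, 0.05, 0.9)
  expect_equal(normalize_af(a, b), a / b)
  expect_error(normalize_af(0, 0.5), "0, 1")
  expect_error(normalize_af(0.5, 1.2), "0, 1")
})

test_that("cohort AF normalization pairs against the max-AF same-tumor driver", {
  m <- rbind(
    make_mutations(sample_id = "s1", gene = "PTEN", allele_fraction = 0.2),
    make_mutations(sample_id = "s1", gene = "APC", allele_fraction = 0.4),
    make_mutations(sample_id = "s1", gene = "KRAS", allele_fraction = 0.5),
    make_mutations(sample_id = "s2", gene = "PTEN", allele_fraction = 0.3)
  )
  expect_message(res <- cohort_normalized_af(m), "dropped")
  expect_equal(nrow(res), 1)
  expect_equal(res$normalized_af, 0.2 / 0.5) # max of APC/KRAS reference
})

test_that("KS comparisons: trivial cases, exact small-sample p, monotone invariance", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compare_af(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  disjoint <- compare_af(x, x + 10)
  expect_equal(disjoint$D, 1)
  # exact p equals full enumeration for n = m = 5
  set.seed(79)
  a <- runif(5)
  b <- runif(5)
  res <- compare_af(a, b)
  expect_true(res$exact)
  combs <- combn(10, 5)
  pool <- c(a, b)
  d_of <- function(idx) {
    g1 <- sort(pool[idx]); g2 <- sort(pool[-idx])
    grid <- sort(pool)
    max(abs(ecdf(g1)(grid) - ecdf(g2)(grid)))
  }
  d_obs <- d_of(1:5)
  p_exact <- mean(apply(combs, 2, d_of) >= d_obs - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
  # D invariant under strictly monotone transforms
  res_t <- compare_af(log(a + 1), log(b + 1))
  expect_equal(res_t$D, res$D)
})

test_that("stratified frequencies carry Wilson intervals and a Fisher equality test", {
  m <- data.frame(
    sample_id = as.character(1:150), subtype = "MT-L",
    stage = rep(c("I+II", "III+IV", "unknown"), c(100, 40, 10)),
    PTEN.mutation_any = c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 4), rep(FALSE, 36), rep(FALSE, 10))
  )
  res <- frequency_by_stratum(m, "PTEN.mutation_any")
  tab <- res$table
  expect_equal(tab$stratum, c("I+II", "III+IV"))
  expect_equal(tab$frequency, c(0.10, 0.10))
  w <- wilson_ci(10, 100)
  expect_equal(tab$ci_low[1], unname(w["lower"]))
  expect_equal(round(w, 3), c(lower = 0.055, upper = 0.174), tolerance = 1e-2)
  expect_gt(res$p_equal, 0.9) # equal frequencies
  # zero events: frequency 0 with a positive upper bound
  m0 <- data.frame(
    sample_id = as.character(1:50), subtype = "MT-L", stage = "I+II",
    PTEN.mutation_any = FALSE
  )
  res0 <- frequency_by_stratum(m0, "PTEN.mutation_any")
  expect_equal(res0$table$frequency, 0)
  expect_equal(res0$table$ci_low, 0)
  expect_gt(res0$table$ci_high, 0)
  expect_true(is.na(res0$p_equal))
})
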