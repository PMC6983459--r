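test_that("collapsing counts subjects, not alleles, and validates cohort assignment", {
  ts <- toy_study()
  counts <- collapse_carriers(ts$carriers, ts$cohorts)
  expect_equal(counts$a, 2L)  # A02 carries two variants but counts once
  expect_equal(counts$c, 1L)
  expect_equal(counts$n1, 20L)
  expect_equal(counts$n2, 30L)
  orphan <- rbind(ts$carriers, data.frame(subject_id = "ZZ", variant_id = "v1"))
  expect_error(collapse_carriers(orphan, ts$cohorts), "no cohort")
  dup <- rbind(ts$cohorts, data.frame(subject_id = "A01", cohort = "control"))
  expect_error(collapse_carriers(ts$carriers, dup), "more than one cohort")
  # restriction to qualifying variants
  expect_equal(collapse_carriers(ts$carriers, ts$cohorts, "v4")$a, 0L)
})

test_that("collapsing equals a brute-force row-wise any() over random carrier matrices", {
  set.seed(99)
  for (i in 1:20) {
    n_sub <- sample(10:40, 1); n_var <- sample(1:8, 1)
    mat <- matrix(runif(n_sub * n_var) < 0.2, n_sub, n_var,
                  dimnames = list(sprintf("s%02d", 1:n_sub), sprintf("v%d", 1:n_var)))
    cohort <- sample(c("case", "control"), n_sub, replace = TRUE, prob = c(0.4, 0.6))
    cohort[1:2] <- c("case", "control")  # both cohorts non-empty
    idx <- which(mat, arr.ind = TRUE)
    carriers <- data.frame(subject_id = rownames(mat)[idx[, 1]],
                           variant_id = colnames(mat)[idx[, 2]])
    counts <- collapse_carriers(carriers, data.frame(subject_id = rownames(mat),
                                                     cohort = cohort))
    carrier_any <- apply(mat, 1, any)
    expect_equal(counts$a, sum(carrier_any & cohort == "case"))
    expect_equal(counts$c, sum(carrier_any & cohort == "control"))
  }
})

test_that("one-sided Fisher matches printed-table closed forms", {
  expect_equal(fisher_one_sided(collapsed_counts(1, 574, 0, 828)), 574 / 1402)
  expect_equal(round(fisher_one_sided(collapsed_counts(1, 574, 0, 828)), 2), 0.41)
  expect_equal(fisher_one_sided(collapsed_counts(0, 574, 5, 828)), 1.0)
})

test_that("one-sided Fisher equals the enumeration oracle on random tables and is monotone in a", {
  set.seed(123)
  for (i in 1:200) {
    ct <- random_counts(60)
    expect_equal(fisher_one_sided(ct),
                 fisher_enum_oracle(ct$a, ct$n1, ct$c, ct$n2), tolerance = 1e-12)
  }
  # cross-check against the reference implementation in stats
  for (i in 1:25) {
    ct <- random_counts(60)
    m <- matrix(c(ct$a, ct$n1 - ct$a, ct$c, ct$n2 - ct$c), 2, byrow = TRUE)
    expect_equal(fisher_one_sided(ct),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  # monotone decreasing in a at fixed margins, and always in (0, 1]
  for (n1 in c(5, 20)) {
    k <- 6; n2 <- 25
    p <- sapply(0:min(k, n1), function(a) fisher_one_sided(collapsed_counts(a, n1, k - a, n2)))
    expect_true(all(diff(p) < 0))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("one-sided chi-square is the signed half of the textbook Pearson p", {
  # perfectly proportional table -> statistic 0 -> one-sided p exactly 0.5
  expect_equal(chisq_one_sided(collapsed_counts(4, 40, 6, 60)), 0.5)
  set.seed(321)
  for (i in 1:50) {
    ct <- random_counts(200)
    if (ct$a + ct$c == 0 || (ct$n1 - ct$a) + (ct$n2 - ct$c) == 0) next
    x2 <- chisq_stat_oracle(ct$a, ct$n1, ct$c, ct$n2)
    half <- pchisq(x2, 1, lower.tail = FALSE) / 2
    expected <- if (ct$a / ct$n1 >= ct$c / ct$n2) half else 1 - half
    expect_equal(chisq_one_sided(ct), expected, tolerance = 1e-12)
    # direction flip: transposing cohorts maps p -> 1 - p
    flip <- chisq_one_sided(collapsed_counts(ct$c, ct$n2, ct$a, ct$n1))
    expect_equal(flip + chisq_one_sided(ct), 1, tolerance = 1e-12)
  }
  # continuity-corrected statistic agrees with stats::chisq.test
  ct <- collapsed_counts(16, 574, 14, 828)
  m <- matrix(c(16, 558, 14, 814), 2, byrow = TRUE)
  expect_equal(chisq_one_sided(ct, correct = TRUE),
               chisq.test(m, correct = TRUE)$p.value / 2, tolerance = 1e-12)
  expect_warning(p <- chisq_one_sided(collapsed_counts(0, 10, 0, 10)), "degenerate")
  expect_equal(p, 1)
})

test_that("odds ratio is the cross-product with Woolf interval; zero cells yield NA, never infinity", {
  res <- odds_ratio(collapsed_counts(8, 574, 3, 828))
  expect_equal(res$or, (8 * 825) / (3 * 566))
  expect_equal(round(res$or, 1), 3.9)
  se <- sqrt(1 / 8 + 1 / 566 + 1 / 3 + 1 / 825)
  expect_equal(res$ci_low, exp(log(res$or) - qnorm(0.975) * se))
  expect_equal(round(odds_ratio(collapsed_counts(8, 574, 11, 828))$or, 1), 1.0)
  # balanced design, equal rates -> OR exactly 1
  expect_equal(odds_ratio(collapsed_counts(5, 50, 5, 50))$or, 1)
  deg <- odds_ratio(collapsed_counts(0, 10, 3, 20))
  expect_true(is.na(deg$or) && is.na(deg$ci_low))
  # transposing cohorts gives the reciprocal
  set.seed(17)
  for (i in 1:20) {
    ct <- random_counts(80)
    o1 <- odds_ratio(ct)$or
    o2 <- odds_ratio(collapsed_counts(ct$c, ct$n2, ct$a, ct$n1))$or
    if (!is.na(o1)) expect_equal(o1, 1 / o2, tolerance = 1e-12)
  }
})

test_that("the stratified table renders the expected layout on the packaged case study", {
  cs <- fbn1_case_study()
  v <- classify_variants(cs$variants[is_novel(cs$variants), ])
  tab <- stratified_burden(v, cs$carriers, cs$cohorts)
  df <- as.data.frame(tab)
  get <- function(lab) df[trimws(df$stratum) == lab, ]
  expect_equal(unlist(get("Total")[, c("n_variants", "a", "c")], use.names = FALSE),
               c(30, 16, 14))
  expect_equal(unlist(get("CADD score < 20")[, c("n_variants", "a", "c")], use.names = FALSE),
               c(19, 8, 11))
  expect_equal(unlist(get("CADD score >= 20")[, c("n_variants", "a", "c")], use.names = FALSE),
               c(11, 8, 3))
  expect_equal(unlist(get("Frameshift")[, c("n_variants", "a", "c")], use.names = FALSE),
               c(1, 0, 1))
  expect_equal(unlist(get("Splicing")[, c("n_variants", "a", "c")], use.names = FALSE),
               c(1, 1, 0))
  expect_equal(unlist(get("Missense")[1, c("n_variants", "a", "c")], use.names = FALSE),
               c(17, 7, 10))
  dmis <- get("CADD score >= 20")
  expect_equal(round(dmis$odds_ratio, 1), 3.9)
  expect_equal(round(dmis$p_value, 2), 0.03)
  expect_equal(round(get("CADD score < 20")$p_value, 2), 0.55)
  expect_equal(round(get("Splicing")$p_value, 2), 0.41)
  # degenerate cells render "-" in the text replica
  expect_match(paste(capture.output(print(tab)), collapse = "\n"), "Frameshift.*-")
})

test_that("an empty variant set yields zero-count rows with undefined P", {
  ts <- toy_study()
  empty <- ts$variants[0, ]
  tab <- stratified_burden(empty, ts$carriers, ts$cohorts)
  expect_equal(as.data.frame(tab)$n_variants[1], 0)
  expect_true(is.na(as.data.frame(tab)$p_value[1]))
})

test_that("allele-level counting uses 2N denominators behind the counting flag", {
  ts <- toy_study()
  tab <- stratified_burden(ts$variants, ts$carriers, ts$cohorts, counting = "allele")
  df <- as.data.frame(tab)
  expect_equal(df$n1[1], 40L)
  expect_equal(df$n2[1], 60L)
  expect_equal(df$a[1], 3L)  # carrier observations, not distinct subjects
})
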