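# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::phyper/pchisq) so a shared bug
# cannot cancel out.

# exact upper-tail hypergeometric probability by direct enumeration of
# binomial coefficients: P(X >= a) for X ~ Hypergeom(n1, n2, k = a + c)
fisher_enum_oracle <- function(a, n1, c, n2) {
  k <- a + c
  ks <- max(0, k - n2):min(n1, k)
  mass <- choose(n1, ks) * choose(n2, k - ks) / choose(n1 + n2, k)
  sum(mass[ks >= a])
}

# textbook Pearson statistic on the carrier/non-carrier 2x2
chisq_stat_oracle <- function(a, n1, c, n2) {
  b <- n1 - a; d <- n2 - c; n <- n1 + n2
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force linear scan for domain membership
domain_scan_oracle <- function(pos, starts, ends, names) {
  for (i in seq_along(starts)) {
    if (starts[i] <= pos && pos <= ends[i]) return(names[i])
  }
  "inter-domain"
}

random_counts <- function(max_n = 60) {
  n1 <- sample(1:(max_n - 1), 1)
  n2 <- sample(1:(max_n - n1), 1)
  collapsed_counts(sample(0:n1, 1), n1, sample(0:n2, 1), n2)
}

# small qualifying variant table + carriers + cohorts for plumbing tests
toy_study <- function(n_cases = 20, n_controls = 30) {
  variants <- variant_table(
    chrom = "1", pos = c(100, 200, 300, 400), ref = "A", alt = "T",
    gene = "G1", consequence = c("missense", "missense", "frameshift", "splice_site"),
    cadd = c(25, 10, 35, 12),
    variant_id = paste0("v", 1:4),
    af = list(`1KG` = NA_real_, ESP = NA_real_, ExAC = NA_real_,
              dbSNP = NA_real_, UMD = NA_real_)
  )
  cohorts <- data.frame(
    subject_id = c(sprintf("A%02d", 1:n_cases), sprintf("B%02d", 1:n_controls)),
    cohort = rep(c("case", "control"), c(n_cases, n_controls))
  )
  carriers <- data.frame(subject_id = c("A01", "A02", "A02", "B01"),
                         variant_id = c("v1", "v2", "v3", "v4"))
  list(variants = variants, carriers = carriers, cohorts = cohorts)
}
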