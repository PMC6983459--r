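#' Collapsed 2x2 carrier counts
#'
#' The contingency table every burden statistic consumes: `a` carriers among
#' `n1` cases, `c` carriers among `n2` controls. Carrier status is
#' subject-level: a subject with several qualifying variants counts once.
#'
#' @param a carrier count in cases.
#' @param n1 case cohort size.
#' @param c carrier count in controls.
#' @param n2 control cohort size.
#' @return object of class `collapsed_counts`.
#' @export
collapsed_counts <- function(a, n1, c, n2) {
  a <- as.integer(a); n1 <- as.integer(n1); c <- as.integer(c); n2 <- as.integer(n2)
  if (a < 0 || c < 0 || a > n1 || c > n2) {
    stop("invalid counts: need 0 <= a <= n1 and 0 <= c <= n2")
  }
  structure(list(a = a, n1 = n1, c = c, n2 = n2), class = "collapsed_counts")
}

#' @export
print.collapsed_counts <- function(x, ...) {
  cat(sprintf("carriers: %d/%d cases vs %d/%d controls\n", x$a, x$n1, x$c, x$n2))
  invisible(x)
}

#' Collapse qualifying variants to subject-level carrier counts
#'
#' CAST-style collapsing: each subject is reduced to a carrier indicator
#' (at least one qualifying variant) and the indicator is cross-tabulated
#' against cohort membership.
#'
#' @param carriers `data.frame` with columns `subject_id`, `variant_id`
#'   (one row per carried variant).
#' @param cohorts `data.frame` with columns `subject_id`, `cohort`
#'   (`"case"` or `"control"`), one row per subject in the study.
#' @param variant_ids optional restriction to a set of qualifying variants;
#'   default uses every variant present in `carriers`.
#' @return a `collapsed_counts`.
#' @export
collapse_carriers <- function(carriers, cohorts, variant_ids = NULL) {
  stopifnot(all(c("subject_id", "variant_id") %in% names(carriers)),
            all(c("subject_id", "cohort") %in% names(cohorts)))
  if (anyDuplicated(cohorts$subject_id)) stop("subject assigned to more than one cohort")
  bad <- !cohorts$cohort %in% c("case", "control")
  if (any(bad)) stop("cohort labels must be 'case' or 'control'")
  if (!is.null(variant_ids)) {
    carriers <- carriers[carriers$variant_id %in% variant_ids, , drop = FALSE]
  }
  unknown <- setdiff(carriers$subject_id, cohorts$subject_id)
  if (length(unknown)) {
    stop("genotyped subject(s) in no cohort: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  carrier_ids <- unique(carriers$subject_id)
  is_case <- cohorts$cohort == "case"
  collapsed_counts(
    a  = sum(cohorts$subject_id[is_case] %in% carrier_ids),
    n1 = sum(is_case),
    c  = sum(cohorts$subject_id[!is_case] %in% carrier_ids),
    n2 = sum(!is_case)
  )
}

#' One-sided Fisher exact test for carrier enrichment in cases
#'
#' Exact hypergeometric upper-tail probability of observing at least the
#' seen number of case carriers, conditional on both margins (alternative:
#' carriers are enriched in cases). Always in (0, 1].
#'
#' @param counts a `collapsed_counts`.
#' @return the one-sided P value.
#' @export
fisher_one_sided <- function(counts) {
  stopifnot(inherits(counts, "collapsed_counts"))
  # P(X >= a), X ~ Hypergeom(n1 cases, n2 controls, a+c carriers drawn)
  stats::phyper(counts$a - 1, counts$n1, counts$n2, counts$a + counts$c,
                lower.tail = FALSE)
}

#' One-sided Pearson chi-square test for carrier enrichment in cases
#'
#' Half the two-sided 1-df Pearson chi-square P value when the observed
#' case carrier fraction exceeds the control fraction, and one minus that
#' half otherwise; a perfectly proportional table gives exactly 0.5.
#'
#' @param counts a `collapsed_counts`.
#' @param correct apply Yates continuity correction; default `FALSE`.
#' @return the one-sided P value.
#' @export
chisq_one_sided <- function(counts, correct = FALSE) {
  stopifnot(inherits(counts, "collapsed_counts"))
  a <- as.numeric(counts$a); b <- as.numeric(counts$n1 - counts$a)
  c <- as.numeric(counts$c); d <- as.numeric(counts$n2 - counts$c)
  if (a + c == 0 || b + d == 0) {
    warning("degenerate carrier margin; one-sided chi-square P set to 1")
    return(1)
  }
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  x2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  half <- stats::pchisq(x2, df = 1, lower.tail = FALSE) / 2
  if (a / counts$n1 >= c / counts$n2) half else 1 - half
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' OR = (a (n2-c)) / (c (n1-a)) on the carrier/non-carrier table, with the
#' Woolf log-scale 95% interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/(n1-a) + 1/c + 1/(n2-c))).
#' Any zero cell makes the estimate degenerate; `NA` is returned (reports
#' render it "-"), never infinity.
#'
#' @param counts a `collapsed_counts`.
#' @param conf_level confidence level, default 0.95.
#' @return list with `or`, `ci_low`, `ci_high` (all `NA` when degenerate).
#' @export
odds_ratio <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "collapsed_counts"))
  a <- as.numeric(counts$a); b <- as.numeric(counts$n1 - counts$a)
  c <- as.numeric(counts$c); d <- as.numeric(counts$n2 - counts$c)
  if (min(a, b, c, d) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  or <- (a * d) / (c * b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

# Table-layout strata: the deleteriousness split places every variant that
# is not damaging-missense in the "CADD < threshold" group (the printed
# table files frameshift/splicing LGD rows there), with mutation-type
# sub-rows for whichever consequences are present.
stratum_layout <- function(variants, cadd_threshold) {
  dmis <- variants$consequence == "missense" &
    !is.na(variants$cadd) & variants$cadd >= cadd_threshold
  sub_labels <- c(frameshift = "  Frameshift", splice_site = "  Splicing",
                  nonsense = "  Nonsense", inframe_indel = "  In-frame indel",
                  missense = "  Missense", synonymous = "  Synonymous",
                  other = "  Other")
  lo <- which(!dmis)
  strata <- list(list(label = "Total", idx = seq_len(nrow(variants))),
                 list(label = sprintf("CADD score < %s", cadd_threshold), idx = lo))
  for (cons in names(sub_labels)) {
    idx <- lo[variants$consequence[lo] == cons]
    if (length(idx)) strata <- c(strata, list(list(label = sub_labels[[cons]], idx = idx)))
  }
  strata <- c(strata,
              list(list(label = sprintf("CADD score >= %s", cadd_threshold), idx = which(dmis)),
                   list(label = "  Missense", idx = which(dmis & variants$consequence == "missense"))))
  strata
}

#' Stratified collapsing burden analysis
#'
#' Runs the subject-level collapsing test per deleteriousness stratum and
#' renders the classical layout: a Total row, the CADD-below-threshold
#' group with mutation-type sub-rows, and the damaging-missense
#' (CADD-at-or-above-threshold) group. The variant count per row is the
#' number of qualifying carrier observations (a recurrent variant counts
#' once per carrier); the distinct-variant count is carried alongside.
#'
#' Fisher's exact test is forced for any row whose expected carrier cell
#' drops below 5; otherwise the configured test is used.
#'
#' @param variants qualifying (novelty-filtered, QC-passed) `variant_table`.
#' @param carriers long carrier `data.frame` (subject_id, variant_id).
#' @param cohorts subject-to-cohort assignment (subject_id, cohort).
#' @param cadd_threshold inclusive D-mis CADD cutoff, default 20.
#' @param test `"fisher"` (default) or `"chisq"`.
#' @param correct continuity correction for the chi-square path.
#' @param counting `"subject"` (default; carrier indicator per subject) or
#'   `"allele"` (carrier observations over 2N alleles).
#' @return `data.frame` of class `burden_table`, one row per stratum.
#' @export
stratified_burden <- function(variants, carriers, cohorts, cadd_threshold = 20,
                              test = c("fisher", "chisq"), correct = FALSE,
                              counting = c("subject", "allele")) {
  test <- match.arg(test)
  counting <- match.arg(counting)
  carriers <- carriers[carriers$variant_id %in% variants$variant_id, , drop = FALSE]
  strata <- stratum_layout(variants, cadd_threshold)
  is_case <- cohorts$cohort == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  case_ids <- cohorts$subject_id[is_case]

  rows <- lapply(strata, function(s) {
    ids <- variants$variant_id[s$idx]
    cc <- carriers[carriers$variant_id %in% ids, , drop = FALSE]
    n_obs <- nrow(cc)
    if (counting == "subject") {
      counts <- collapse_carriers(cc, cohorts)
    } else {
      counts <- collapsed_counts(sum(cc$subject_id %in% case_ids), 2L * n1,
                                 sum(!cc$subject_id %in% case_ids), 2L * n2)
    }
    or <- odds_ratio(counts)
    if (n_obs == 0) {
      p <- NA_real_; used <- NA_character_
    } else {
      k <- counts$a + counts$c
      expected_min <- k * min(counts$n1, counts$n2) / (counts$n1 + counts$n2)
      used <- if (test == "chisq" && expected_min >= 5) "chisq_one_sided" else "fisher_one_sided"
      p <- if (used == "chisq_one_sided") chisq_one_sided(counts, correct = correct)
           else fisher_one_sided(counts)
    }
    data.frame(stratum = s$label, n_variants = n_obs,
               n_distinct = length(unique(cc$variant_id)),
               a = counts$a, n1 = counts$n1, c = counts$c, n2 = counts$n2,
               odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               p_value = p, test = used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cadd_threshold") <- cadd_threshold
  attr(out, "counting") <- counting
  class(out) <- unique(c("burden_table", class(out)))
  out
}

fmt_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), "-", sprintf("%.1f (%.1f-%.1f)", or, lo, hi))
}

#' @export
print.burden_table <- function(x, ...) {
  df <- as.data.frame(x)
  lines <- sprintf("%-22s %6d %6d %6d   %-18s %s",
                   df$stratum, df$n_variants, df$a, df$c,
                   fmt_or_ci(df$odds_ratio, df$ci_low, df$ci_high),
                   ifelse(is.na(df$p_value), "-", sprintf("%.2f", df$p_value)))
  cat(sprintf("Mutational burden (%s-level collapsing; cases n=%d, controls n=%d)\n",
              attr(x, "counting"), df$n1[1], df$n2[1]))
  cat(sprintf("%-22s %6s %6s %6s   %-18s %s\n",
              "Stratum", "Nvar", "Case", "Ctrl", "OR (95% CI)", "P"))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.burden_table <- function(object, ...) {
  print(object)
  sig <- as.data.frame(object)
  sig <- sig[!is.na(sig$p_value) & sig$p_value < 0.05, "stratum"]
  if (length(sig)) cat("Strata with P < 0.05:", paste(trimws(sig), collapse = ", "), "\n")
  invisible(object)
}

#' Write a burden table as TSV / JSON
#' @param tab a `burden_table`.
#' @param path output path.
#' @export
write_burden_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_burden_tsv
#' @export
write_burden_json <- function(tab, path) {
  jsonlite::write_json(as.data.frame(tab), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
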