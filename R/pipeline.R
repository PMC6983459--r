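#' Assemble and validate a pipeline run configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' objects. Every under-specified default (novelty resource list, CADD
#' cutoff, pruning threshold, test recipe, counting mode) is resolved here
#' and embedded verbatim in the run report so it is auditable.
#'
#' @param variants variant table or TSV/VCF path.
#' @param carriers carrier `data.frame` (subject_id, variant_id); implied
#'   when `variants` is a VCF.
#' @param cohorts cohort assignment `data.frame` or TSV path.
#' @param coverage optional `coverage_sites` or TSV path; when absent no
#'   harmonization is applied.
#' @param gene optional gene symbol to restrict the analysis to.
#' @param novelty_resources resources defining novelty.
#' @param cadd_threshold inclusive D-mis cutoff.
#' @param max_abs_diff coverage pruning threshold.
#' @param test,correct,counting burden test configuration
#'   (see [stratified_burden()]).
#' @param seed integer seed recorded in the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(variants, carriers = NULL, cohorts, coverage = NULL,
                       gene = NULL,
                       novelty_resources = c("1KG", "ESP", "ExAC", "dbSNP", "UMD"),
                       cadd_threshold = 20, max_abs_diff = 0.10,
                       test = "fisher", correct = FALSE, counting = "subject",
                       seed = 1L) {
  if (is.character(variants)) {
    if (grepl("\\.vcf(\\.gz)?$", variants, ignore.case = TRUE)) {
      vcf <- read_variant_vcf(variants)
      if (is.null(carriers)) carriers <- vcf$carriers
      variants <- vcf$variants
    } else {
      variants <- read_variant_tsv(variants)
    }
  }
  if (is.null(carriers)) stop("carriers are required (directly or via a VCF)")
  if (is.character(cohorts)) cohorts <- utils::read.delim(cohorts, stringsAsFactors = FALSE)
  if (is.character(coverage)) coverage <- read_coverage_tsv(coverage)
  structure(list(variants = variants, carriers = carriers, cohorts = cohorts,
                 coverage = coverage, gene = gene,
                 novelty_resources = novelty_resources,
                 cadd_threshold = cadd_threshold, max_abs_diff = max_abs_diff,
                 test = test, correct = correct, counting = counting,
                 seed = as.integer(seed)),
            class = "run_config")
}

resolved_config <- function(config) {
  list(gene = config$gene, novelty_resources = config$novelty_resources,
       cadd_threshold = config$cadd_threshold,
       max_abs_diff = config$max_abs_diff, test = config$test,
       continuity_correction = config$correct, counting = config$counting,
       seed = config$seed)
}

#' Run the case-control burden stage
#'
#' Stage order: coverage harmonization (site pruning), QC filter, novelty
#' filter, LGD/D-mis classification, stratified subject-level collapsing
#' burden tests.
#'
#' @param config a `run_config`.
#' @return list of class `burden_report`: the resolved config, a
#'   harmonization summary, the variant accounting per stage, and the
#'   `burden_table`.
#' @export
run_burden <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$variants
  if (!is.null(config$gene)) v <- v[v$gene == config$gene, , drop = FALSE]
  n_input <- nrow(v)

  harm <- NULL
  if (!is.null(config$coverage)) {
    harm <- harmonize(config$coverage, config$max_abs_diff)
    v <- apply_harmonization(v, harm)
  }
  n_after_harm <- nrow(v)
  v <- v[v$qc_pass, , drop = FALSE]
  v <- v[is_novel(v, config$novelty_resources), , drop = FALSE]
  n_after_novelty <- nrow(v)
  v <- classify_variants(v, config$cadd_threshold)
  tab <- stratified_burden(v, config$carriers, config$cohorts,
                           cadd_threshold = config$cadd_threshold,
                           test = config$test, correct = config$correct,
                           counting = config$counting)
  structure(list(
    config = resolved_config(config),
    harmonization = if (is.null(harm)) NULL else
      list(n_sites = nrow(harm$retained) + nrow(harm$excluded),
           n_excluded = nrow(harm$excluded),
           excluded_fraction = harm$excluded_fraction),
    n_variants_input = n_input,
    n_variants_after_harmonization = n_after_harm,
    n_qualifying_variants = n_after_novelty,
    variants = v,
    burden = tab
  ), class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("Rare-variant collapsing burden report\n")
  if (!is.null(x$harmonization)) {
    cat(sprintf("  harmonization: %d/%d sites excluded (%.1f%%)\n",
                x$harmonization$n_excluded, x$harmonization$n_sites,
                100 * x$harmonization$excluded_fraction))
  }
  cat(sprintf("  variants: %d input -> %d after site pruning -> %d qualifying (novel, QC-pass)\n",
              x$n_variants_input, x$n_variants_after_harmonization,
              x$n_qualifying_variants))
  print(x$burden)
  invisible(x)
}

#' Run the family cosegregation stage
#'
#' Screens candidate variants for full-penetrance dominant cosegregation,
#' ranks the survivors (LGD before damaging missense, then CADD), and
#' combines any supplied ACMG evidence codes into pathogenicity classes.
#'
#' @param ped a `pedigree`.
#' @param variants candidate `variant_table`.
#' @param evidence optional named list: variant_id -> character vector of
#'   ACMG codes.
#' @param cadd_threshold D-mis cutoff used for ranking.
#' @param tolerated_unaffected_carriers see [dominant_candidates()].
#' @return list of class `family_report` with `verdicts`, `ranked` and
#'   `acmg`.
#' @export
run_family <- function(ped, variants, evidence = list(), cadd_threshold = 20,
                       tolerated_unaffected_carriers = 0) {
  verdicts <- dominant_candidates(ped, variants, tolerated_unaffected_carriers)
  ranked <- rank_candidates(verdicts, classify_variants(variants, cadd_threshold))
  acmg <- NULL
  if (length(evidence)) {
    acmg <- do.call(rbind, lapply(names(evidence), function(vid) {
      res <- combine_evidence(evidence[[vid]])
      data.frame(variant_id = vid, class = res$class, rule_fired = res$rule_fired,
                 codes = paste(evidence[[vid]], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(verdicts = verdicts, ranked = ranked, acmg = acmg,
                 candidates = ranked$variant_id[ranked$cosegregates]),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat("Dominant cosegregation report\n")
  cat(sprintf("  %d candidate variant(s); %d cosegregate\n",
              nrow(x$verdicts), sum(x$verdicts$cosegregates)))
  if (length(x$candidates)) {
    cat("  ranked cosegregating candidates:", paste(x$candidates, collapse = ", "), "\n")
  }
  if (!is.null(x$acmg)) {
    for (i in seq_len(nrow(x$acmg))) {
      cat(sprintf("  ACMG %s [%s] -> %s\n", x$acmg$variant_id[i],
                  x$acmg$codes[i], x$acmg$class[i]))
    }
  }
  invisible(x)
}

#' Write a burden report to a directory
#'
#' Emits `burden.tsv`, `burden.json` (rows plus the resolved config and
#' stage accounting) and `burden.txt` (the fixed-width table replica).
#'
#' @param report a `burden_report`.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_burden_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "burden.tsv")
  write_burden_tsv(report$burden, tsv)
  js <- file.path(dir, "burden.json")
  jsonlite::write_json(list(config = report$config,
                            harmonization = report$harmonization,
                            n_variants_input = report$n_variants_input,
                            n_qualifying_variants = report$n_qualifying_variants,
                            rows = as.data.frame(report$burden)),
                       js, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  txt <- file.path(dir, "burden.txt")
  con <- file(txt, "w"); sink(con); print(report); sink(); close(con)
  invisible(c(tsv, js, txt))
}
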