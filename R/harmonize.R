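#' Fraction of subjects with adequate coverage at a site
#'
#' @param depths per-subject read depths at one site.
#' @param min_depth depth constituting "adequate" coverage; default 10x,
#'   a common exome QC convention (surfaced here so it is never silent).
#' @return fraction in \[0, 1\].
#' @export
adequate_fraction <- function(depths, min_depth = 10) {
  if (!length(depths)) stop("empty cohort: no depths supplied")
  mean(depths >= min_depth)
}

#' Build a coverage-site table
#' @param chrom,pos site coordinates (1-based).
#' @param frac_cases,frac_controls fraction of each cohort with adequate
#'   coverage at the site, in \[0, 1\].
#' @return `data.frame` of class `coverage_sites`.
#' @export
coverage_sites <- function(chrom, pos, frac_cases, frac_controls) {
  if (any(frac_cases < 0 | frac_cases > 1) || any(frac_controls < 0 | frac_controls > 1)) {
    stop("coverage fractions must lie in [0,1]")
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   frac_cases = as.numeric(frac_cases),
                   frac_controls = as.numeric(frac_controls),
                   stringsAsFactors = FALSE)
  class(df) <- unique(c("coverage_sites", class(df)))
  df
}

#' Site-based coverage harmonization between cohorts
#'
#' Excludes every coding site whose case and control adequate-coverage
#' fractions differ by more than `max_abs_diff` (strict inequality on the
#' absolute difference, i.e. percentage points, default 10). This prevents
#' differential-missingness artifacts from inflating the burden test.
#'
#' @param sites a `coverage_sites` table.
#' @param max_abs_diff exclusion threshold on |frac_cases - frac_controls|;
#'   a site at exactly the threshold is retained.
#' @return object of class `harmonization_result`: list with `retained`
#'   and `excluded` site tables and `excluded_fraction`.
#' @export
harmonize <- function(sites, max_abs_diff = 0.10) {
  stopifnot(max_abs_diff >= 0, max_abs_diff <= 1)
  diff <- abs(sites$frac_cases - sites$frac_controls)
  drop <- diff > max_abs_diff
  structure(list(
    retained = sites[!drop, , drop = FALSE],
    excluded = sites[drop, , drop = FALSE],
    excluded_fraction = if (nrow(sites)) mean(drop) else 0,
    max_abs_diff = max_abs_diff
  ), class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  n <- nrow(x$retained) + nrow(x$excluded)
  cat(sprintf("Coverage harmonization: %d sites, %d excluded (%.1f%%) at |diff| > %.2f\n",
              n, nrow(x$excluded), 100 * x$excluded_fraction, x$max_abs_diff))
  invisible(x)
}

#' Read / write the coverage TSV (chrom, pos, frac_cases, frac_controls)
#' @param path TSV path.
#' @return a `coverage_sites` table.
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  coverage_sites(df$chrom, df$pos, df$frac_cases, df$frac_controls)
}

#' @rdname read_coverage_tsv
#' @param sites a `coverage_sites` table to write.
#' @export
write_coverage_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write excluded sites as BED (0-based half-open)
#'
#' @param result a `harmonization_result`.
#' @param path output BED path.
#' @export
write_excluded_bed <- function(result, path) {
  ex <- result$excluded
  bed <- data.frame(chrom = ex$chrom, start = ex$pos - 1L, end = ex$pos)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop variants falling on excluded sites
#'
#' @param variants a `variant_table`.
#' @param result a `harmonization_result`.
#' @return the variant table restricted to retained sites (variants at
#'   sites absent from the coverage table are kept: no coverage evidence,
#'   no exclusion).
#' @export
apply_harmonization <- function(variants, result) {
  key <- function(chrom, pos) paste0(chrom, ":", pos)
  drop <- key(variants$chrom, variants$pos) %in% key(result$excluded$chrom, result$excluded$pos)
  variants[!drop, , drop = FALSE]
}
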