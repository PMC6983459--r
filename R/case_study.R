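#' The packaged FBN1 congenital-scoliosis case study
#'
#' A deterministic dataset reconstructing the published single-gene
#' rare-variant inventory this package was written around: 574 cases and
#' 828 controls; 30 novel qualifying variant observations (28 missense,
#' 1 frameshift, 1 splicing) across 16 case and 14 control carriers;
#' 11 damaging-missense observations (CADD >= 20), 8 in cases (7 distinct
#' variants -- p.Leu871Phe recurs in two unrelated cases, subjects XH73 and
#' XH579) and 3 in controls. The 8 case D-mis records carry their printed
#' genomic positions, HGVS strings, CADD scores and protein domains; all
#' other records (control D-mis, low-CADD missense, frameshift, splicing
#' variants and the non-carrier cohort fill) are synthetic placeholders
#' constructed to reproduce the published stratum counts and are labeled
#' as such. The accompanying three-generation pedigree carries the
#' heterozygous nonsense variant c.2649G>A (p.Trp883Ter, CADD 42) in the
#' affected proband III-1 and his affected mother II-2, with genotyped
#' unaffected relatives non-carriers.
#'
#' Domain intervals are approximate synthetic reconstructions (only the
#' residue-to-domain assignments of the printed records are authoritative);
#' see `inst/extdata/fbn1_domains_synthetic.tsv`.
#'
#' @return list of class `case_study` with `variants`, `carriers`,
#'   `cohorts`, `domain_map`, `pedigree`, `family_variants`, `evidence`
#'   (ACMG codes for the family nonsense variant) and `protein_length`.
#' @export
fbn1_case_study <- function() {
  ext <- function(f) system.file("extdata", f, package = "rvburden")
  dmis <- utils::read.delim(ext("fbn1_dmis_case_variants.tsv"),
                            stringsAsFactors = FALSE)

  # distinct D-mis case variants (the recurrent one collapses to one row)
  dvar <- dmis[!duplicated(dmis$cdna_change), , drop = FALSE]
  d_case <- variant_table(
    chrom = dvar$chrom, pos = dvar$pos, ref = dvar$ref, alt = dvar$alt,
    gene = "FBN1", consequence = "missense", cadd = dvar$cadd,
    cdna_change = dvar$cdna_change, protein_change = dvar$protein_change,
    af = list(`1KG` = NA_real_, ESP = NA_real_, ExAC = NA_real_,
              dbSNP = NA_real_, UMD = NA_real_, gnomAD = dvar$af_gnomAD)
  )

  syn <- function(n, pos0, consequence, cadd, prefix) {
    variant_table(
      chrom = "15", pos = pos0 + seq_len(n) * 100L, ref = "A", alt = "G",
      gene = "FBN1", consequence = consequence, cadd = cadd,
      variant_id = sprintf("%s%02d", prefix, seq_len(n)),
      protein_pos = 300L + seq_len(n),
      af = list(`1KG` = NA_real_, ESP = NA_real_, ExAC = NA_real_,
                dbSNP = NA_real_, UMD = NA_real_, gnomAD = NA_real_)
    )
  }
  d_ctrl <- syn(3, 48700000L, "missense", c(21.5, 25.0, 30.1), "CTRL_DMIS")
  mis_case <- syn(7, 48710000L, "missense", c(5.2, 8.9, 11.3, 14.0, 16.5, 18.2, 19.6), "CASE_MIS")
  mis_ctrl <- syn(10, 48730000L, "missense",
                  c(3.1, 6.4, 7.7, 9.8, 10.5, 12.2, 13.9, 15.1, 17.3, 19.9), "CTRL_MIS")
  spl_case <- syn(1, 48750000L, "splice_site", NA_real_, "CASE_SPL")
  fs_ctrl <- syn(1, 48760000L, "frameshift", NA_real_, "CTRL_FS")

  variants <- rbind(d_case, d_ctrl, mis_case, mis_ctrl, spl_case, fs_ctrl)
  class(variants) <- unique(c("variant_table", class(variants)))

  case_extra <- sprintf("XHC%03d", seq_len(8))   # 7 low-CADD missense + 1 splicing carriers
  ctrl_carriers <- sprintf("NC%03d", seq_len(14))
  carriers <- rbind(
    data.frame(subject_id = dmis$subject_id,
               variant_id = d_case$variant_id[match(dmis$cdna_change, dvar$cdna_change)]),
    data.frame(subject_id = case_extra, variant_id = c(mis_case$variant_id, spl_case$variant_id)),
    data.frame(subject_id = ctrl_carriers,
               variant_id = c(d_ctrl$variant_id, mis_ctrl$variant_id, fs_ctrl$variant_id))
  )
  case_ids <- unique(c(dmis$subject_id, case_extra,
                       sprintf("CS%04d", seq_len(574))))[1:574]
  ctrl_ids <- unique(c(ctrl_carriers, sprintf("CN%04d", seq_len(828))))[1:828]
  cohorts <- data.frame(subject_id = c(case_ids, ctrl_ids),
                        cohort = rep(c("case", "control"), c(574, 828)),
                        stringsAsFactors = FALSE)

  fam <- planted_family()
  fam$variants$variant_id[1] <- "FBN1:c.2649G>A"
  fam$variants$cdna_change <- c("c.2649G>A", NA)
  fam$variants$gene <- "FBN1"
  fam$ped$genotypes$variant_id[fam$ped$genotypes$variant_id == "FAMVAR1"] <- "FBN1:c.2649G>A"

  structure(list(
    variants = variants, carriers = carriers, cohorts = cohorts,
    domain_map = read_domain_map(ext("fbn1_domains_synthetic.tsv"),
                                 protein_length = 2871L),
    pedigree = fam$ped, family_variants = fam$variants,
    evidence = list("FBN1:c.2649G>A" = c("PVS1", "PP1", "PP3", "PP5")),
    protein_length = 2871L
  ), class = "case_study")
}
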