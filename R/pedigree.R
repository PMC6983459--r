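#' Build a pedigree with carrier-state genotypes
#'
#' @param members `data.frame` with columns `id`, `father_id`, `mother_id`
#'   (`NA` or `"0"` for founders), `sex` (1 male, 2 female, 0 unknown) and
#'   `affected` (logical).
#' @param genotypes `data.frame` with columns `id`, `variant_id`, `state`
#'   (`"carrier"`, `"non-carrier"` or `"missing"`); members without a row
#'   for a variant are treated as missing (ungenotyped).
#' @param proband id of the index case; defaults to the first affected
#'   member.
#' @return object of class `pedigree`.
#' @export
pedigree <- function(members, genotypes, proband = NULL) {
  stopifnot(all(c("id", "father_id", "mother_id", "sex", "affected") %in% names(members)),
            all(c("id", "variant_id", "state") %in% names(genotypes)))
  members$father_id[members$father_id %in% c("0", "")] <- NA
  members$mother_id[members$mother_id %in% c("0", "")] <- NA
  for (col in c("father_id", "mother_id")) {
    ref <- members[[col]]
    bad <- !is.na(ref) & !ref %in% members$id
    if (any(bad)) stop("unresolved parental reference: ", paste(ref[bad], collapse = ", "))
  }
  if (!any(members$affected)) stop("pedigree has no affected member")
  if (!all(genotypes$state %in% c("carrier", "non-carrier", "missing"))) {
    stop("genotype states must be carrier / non-carrier / missing")
  }
  unknown <- setdiff(genotypes$id, members$id)
  if (length(unknown)) stop("genotyped id not in pedigree: ", paste(unknown, collapse = ", "))
  if (is.null(proband)) proband <- members$id[members$affected][1]
  structure(list(members = members, genotypes = genotypes, proband = proband),
            class = "pedigree")
}

#' Read a 6-column PED file
#'
#' Standard pre-genotype PED columns: family, id, father, mother, sex,
#' phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown; unknown is
#' treated as unaffected for the dominant filter).
#'
#' @param path PED file path.
#' @return `data.frame` of member records, one pedigree per family id.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family_id", "id", "father_id",
                                        "mother_id", "sex", "phenotype"))
  df$affected <- df$phenotype == 2
  df
}

genotype_state <- function(ped, id, variant_id) {
  g <- ped$genotypes
  hit <- g$state[g$id == id & g$variant_id == variant_id]
  if (length(hit)) hit[1] else "missing"
}

#' Dominant cosegregation screen
#'
#' A variant cosegregates under a fully penetrant autosomal-dominant model
#' iff every genotyped affected member is a (heterozygous) carrier and
#' every genotyped unaffected member is a non-carrier. Missing genotypes
#' are non-informative, never violations, and a verdict based on fewer
#' than two informative members is negative. Phenocopies are out of model:
#' an affected non-carrier is a hard violation.
#'
#' @param ped a `pedigree`; the proband must be genotyped for each variant.
#' @param variants a `variant_table` (or anything with a `variant_id`
#'   column) listing the candidate variants.
#' @param tolerated_unaffected_carriers number of unaffected carriers to
#'   tolerate before calling a violation (reduced-penetrance screens);
#'   default 0, matching full penetrance.
#' @return `data.frame` of class `segregation_verdicts`: one row per
#'   variant with `cosegregates`, `informative_members` and a
#'   comma-separated `violations` member list.
#' @export
dominant_candidates <- function(ped, variants, tolerated_unaffected_carriers = 0) {
  stopifnot(inherits(ped, "pedigree"))
  out <- lapply(variants$variant_id, function(vid) {
    if (genotype_state(ped, ped$proband, vid) == "missing") {
      stop("proband ", ped$proband, " is not genotyped for ", vid)
    }
    states <- vapply(ped$members$id, genotype_state, character(1), ped = ped, variant_id = vid)
    informative <- states != "missing"
    affected <- ped$members$affected
    viol_aff <- informative & affected & states == "non-carrier"
    unaff_carrier <- informative & !affected & states == "carrier"
    # tolerate up to the configured number of unaffected carriers
    viol_unaff <- unaff_carrier
    if (sum(unaff_carrier) <= tolerated_unaffected_carriers) viol_unaff[] <- FALSE
    violations <- ped$members$id[viol_aff | viol_unaff]
    data.frame(variant_id = vid,
               cosegregates = length(violations) == 0 && sum(informative) >= 2,
               informative_members = sum(informative),
               violations = paste(violations, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- unique(c("segregation_verdicts", class(res)))
  res
}

#' Rank cosegregation candidates
#'
#' Cosegregating variants first; within them likely gene-disrupting (LGD)
#' before damaging missense before everything else, then descending CADD;
#' the sort is stable for ties.
#'
#' @param verdicts a `segregation_verdicts` table.
#' @param variants the classified `variant_table` (needs `mutation_class`
#'   and `cadd`) supplying the ordering keys.
#' @return the verdicts joined to class/CADD, reordered.
#' @export
rank_candidates <- function(verdicts, variants) {
  if (!nrow(verdicts)) return(verdicts)
  if (is.null(variants$mutation_class)) variants <- classify_variants(variants)
  m <- match(verdicts$variant_id, variants$variant_id)
  cls <- variants$mutation_class[m]
  cls_rank <- match(cls, c("LGD", "MISSENSE_DMIS", "MISSENSE_NON_DMIS", "OTHER"))
  cls_rank[is.na(cls_rank)] <- 5L
  cadd <- variants$cadd[m]
  cadd[is.na(cadd)] <- -Inf
  o <- order(!verdicts$cosegregates, cls_rank, -cadd, method = "radix")
  out <- verdicts[o, , drop = FALSE]
  out$mutation_class <- cls[o]
  out$cadd <- variants$cadd[m][o]
  rownames(out) <- NULL
  out
}
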