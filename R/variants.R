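#' Construct and validate an annotated variant table
#'
#' The central variant container is a plain `data.frame` with one row per
#' variant and a fixed set of columns. Population allele frequencies are
#' stored one column per resource, named `af_<resource>` (e.g. `af_ExAC`);
#' an `NA` entry means the variant is *absent* from that resource, which is
#' what the novelty filter tests (presence, not frequency).
#'
#' @param chrom chromosome labels.
#' @param pos 1-based genomic coordinates (GRCh37-style).
#' @param ref,alt allele strings.
#' @param gene gene symbol.
#' @param consequence one of `"nonsense"`, `"frameshift"`, `"splice_site"`,
#'   `"inframe_indel"`, `"missense"`, `"synonymous"`, `"other"`.
#' @param cadd pre-computed CADD deleteriousness score (`NA` if unscored).
#' @param variant_id unique identifier; defaults to `chrom:pos:ref>alt`.
#' @param cdna_change,protein_change optional HGVS strings.
#' @param protein_pos 1-based residue index; parsed from `protein_change`
#'   when missing.
#' @param qc_pass logical QC flag, default `TRUE`.
#' @param af named list/data.frame of per-resource allele frequencies;
#'   names become `af_` columns.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, consequence,
                          cadd = NA_real_, variant_id = NULL,
                          cdna_change = NA_character_,
                          protein_change = NA_character_,
                          protein_pos = NA_integer_,
                          qc_pass = TRUE, af = NULL) {
  n <- length(pos)
  df <- data.frame(
    variant_id = if (is.null(variant_id)) paste0(chrom, ":", pos, ":", ref, ">", alt) else variant_id,
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = rep_len(as.character(gene), n),
    cdna_change = rep_len(as.character(cdna_change), n),
    protein_change = rep_len(as.character(protein_change), n),
    protein_pos = rep_len(as.integer(protein_pos), n),
    consequence = rep_len(as.character(consequence), n),
    cadd = rep_len(as.numeric(cadd), n),
    qc_pass = rep_len(as.logical(qc_pass), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(af)) {
    for (res in names(af)) df[[paste0("af_", res)]] <- rep_len(as.numeric(af[[res]]), n)
  }
  # protein position falls back to the integer embedded in the HGVS p. string
  need <- is.na(df$protein_pos) & !is.na(df$protein_change)
  df$protein_pos[need] <- extract_protein_pos(df$protein_change[need])
  validate_variant_table(df)
}

consequence_levels <- c("nonsense", "frameshift", "splice_site",
                        "inframe_indel", "missense", "synonymous", "other")

validate_variant_table <- function(df) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
           "consequence", "cadd", "qc_pass")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("genomic positions must be >= 1 (1-based)")
  bad <- !df$consequence %in% consequence_levels
  if (any(bad)) stop("unknown consequence: ", paste(unique(df$consequence[bad]), collapse = ", "))
  afc <- grep("^af_", names(df), value = TRUE)
  for (col in afc) {
    v <- df[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop("allele frequencies in ", col, " outside [0,1]")
  }
  if (anyDuplicated(df$variant_id)) stop("variant_id must be unique")
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Extract the residue index from an HGVS p. string
#'
#' Pulls the first integer out of strings like `"p.Trp883Ter"`; anything
#' beyond that (no ranges, no frameshift offsets) is out of scope.
#' @param protein_change character vector of HGVS p. strings.
#' @return integer vector (`NA` where no digit is present).
#' @export
extract_protein_pos <- function(protein_change) {
  hit <- regexpr("[0-9]+", protein_change)
  has <- !is.na(protein_change) & hit > 0
  out <- rep(NA_integer_, length(protein_change))
  out[has] <- as.integer(regmatches(protein_change, hit)[has])
  out
}

#' Novelty filter against population-frequency resources
#'
#' A variant is "novel" when it is absent from *every* listed resource.
#' Presence decides, not frequency: a record present at allele frequency 0
#' in a listed resource is not novel. Resources not listed (for example
#' gnomAD under the default list) are annotated but ignored, so a variant
#' can be novel despite a gnomAD entry.
#'
#' @param variants a `variant_table` with `af_<resource>` columns.
#' @param resources character vector of resource names to test; every name
#'   must correspond to an `af_<name>` column.
#' @return logical vector, one entry per variant.
#' @export
is_novel <- function(variants,
                     resources = c("1KG", "ESP", "ExAC", "dbSNP", "UMD")) {
  if (!length(resources)) stop("novelty resource list must be non-empty")
  cols <- paste0("af_", resources)
  missing_res <- resources[!cols %in% names(variants)]
  if (length(missing_res)) {
    stop("unknown novelty resource(s): ", paste(missing_res, collapse = ", "),
         " (no matching af_ column in the variant table)")
  }
  present <- Reduce(`|`, lapply(cols, function(col) !is.na(variants[[col]])))
  if (is.null(present)) present <- rep(FALSE, nrow(variants))
  !present
}

#' Classify variants into LGD / D-mis strata
#'
#' Loss-of-function consequences (nonsense, frameshift, splice-site,
#' in-frame indel) cluster into the likely gene-disrupting (LGD) class.
#' Missense variants split on the CADD score: `cadd >= cadd_threshold`
#' (inclusive, default 20 -- roughly the top 1% most deleterious) is
#' damaging missense (`MISSENSE_DMIS`), below is `MISSENSE_NON_DMIS`.
#' A missense variant without a CADD score is an error, never silently
#' non-damaging.
#'
#' @param variants a `variant_table`.
#' @param cadd_threshold inclusive CADD cutoff for D-mis, default 20.
#' @return the table with a `mutation_class` column added (the raw
#'   `consequence` column is retained so mutation-type strata can be formed).
#' @export
classify_variants <- function(variants, cadd_threshold = 20) {
  cons <- variants$consequence
  unscored <- cons == "missense" & is.na(variants$cadd)
  if (any(unscored)) {
    stop("missense variant(s) without a CADD score cannot be classified: ",
         paste(variants$variant_id[unscored], collapse = ", "))
  }
  cls <- rep("OTHER", length(cons))
  cls[cons %in% c("nonsense", "frameshift", "splice_site", "inframe_indel")] <- "LGD"
  mis <- cons == "missense"
  cls[mis & variants$cadd >= cadd_threshold] <- "MISSENSE_DMIS"
  cls[mis & variants$cadd < cadd_threshold] <- "MISSENSE_NON_DMIS"
  variants$mutation_class <- cls
  variants
}

#' Protein domain map
#'
#' Ordered, non-overlapping 1-based closed residue intervals covering parts
#' of a protein of known length.
#'
#' @param start,end 1-based inclusive residue bounds.
#' @param name domain names.
#' @param protein_length total residue count.
#' @return object of class `domain_map`.
#' @export
domain_map <- function(start, end, name, protein_length) {
  stopifnot(length(start) == length(end), length(end) == length(name))
  o <- order(start)
  start <- as.integer(start[o]); end <- as.integer(end[o]); name <- as.character(name[o])
  if (any(start < 1L) || any(end > protein_length)) {
    stop("domain intervals must lie within [1, protein_length]")
  }
  if (any(start > end)) stop("domain interval with start > end")
  if (length(start) > 1 && any(start[-1] <= end[-length(end)])) {
    stop("domain intervals overlap")
  }
  structure(list(start = start, end = end, name = name,
                 protein_length = as.integer(protein_length)),
            class = "domain_map")
}

#' Read a domain map from TSV (columns start, end, name)
#' @param path TSV file with a header `start  end  name`.
#' @param protein_length total residue count of the protein.
#' @return a `domain_map`.
#' @export
read_domain_map <- function(path, protein_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  domain_map(df$start, df$end, df$name, protein_length)
}

#' Locate a residue in a domain map
#'
#' @param protein_pos residue index (vectorized), 1-based.
#' @param map a `domain_map`.
#' @return the containing domain name per position, or `"inter-domain"`
#'   when no interval contains it.
#' @export
annotate_domain <- function(protein_pos, map) {
  stopifnot(inherits(map, "domain_map"))
  if (any(protein_pos < 1L | protein_pos > map$protein_length)) {
    stop("protein position outside [1, ", map$protein_length, "]")
  }
  vapply(as.integer(protein_pos), function(p) {
    hit <- which(map$start <= p & p <= map$end)
    if (length(hit)) map$name[hit[1]] else "inter-domain"
  }, character(1))
}

#' Residues lost to a premature stop
#'
#' Number of residues from the stop codon position to the C-terminus,
#' inclusive of the stop position itself: `protein_length - stop_codon + 1`.
#' For a 2871-residue protein truncated at codon 883 this is 1989.
#'
#' @param protein_length residue count of the full-length protein.
#' @param stop_codon 1-based residue index of the premature stop.
#' @return integer residue count.
#' @export
truncation_distance <- function(protein_length, stop_codon) {
  if (any(stop_codon < 1L) || any(stop_codon > protein_length)) {
    stop("stop codon position outside [1, protein_length]")
  }
  as.integer(protein_length - stop_codon + 1L)
}

#' Read a flat annotated-variant TSV
#'
#' Expects named columns chrom, pos, ref, alt, gene, consequence, cadd and
#' optionally variant_id, cdna_change, protein_change, protein_pos, qc_pass
#' plus one `af_<resource>` column per frequency resource (empty cells =
#' absent from that resource).
#'
#' @param path TSV path.
#' @return a `variant_table`.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$variant_id)) df$variant_id <- paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  if (is.null(df$cadd)) df$cadd <- NA_real_
  for (col in c("cdna_change", "protein_change")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$protein_pos)) df$protein_pos <- extract_protein_pos(df$protein_change)
  validate_variant_table(df)
}

#' Read variants and carrier genotypes from a VCF
#'
#' Parses a VCF (v4.x, GT genotypes) with `vcfR` and returns the variant
#' table together with the long-format carrier list (one row per subject
#' carrying at least one alternate allele at a variant). INFO keys
#' `GENE`, `CSQ` (consequence word) and `CADD` are picked up when present.
#'
#' @param path VCF file path.
#' @return list with elements `variants` (a `variant_table`) and
#'   `carriers` (`data.frame` with columns subject_id, variant_id).
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_field("GENE")
  csq <- info_field("CSQ")
  cadd <- suppressWarnings(as.numeric(info_field("CADD")))
  vt <- variant_table(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    gene = ifelse(is.na(gene), "", gene),
    consequence = ifelse(is.na(csq), "other", csq),
    cadd = cadd,
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ">", fix$ALT),
                        fix$ID)
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  carrier <- !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0", "1/1", "1|1")
  idx <- which(carrier, arr.ind = TRUE)
  carriers <- data.frame(
    subject_id = colnames(gt)[idx[, "col"]],
    variant_id = vt$variant_id[idx[, "row"]],
    stringsAsFactors = FALSE
  )
  list(variants = vt, carriers = carriers[order(carriers$subject_id, carriers$variant_id), ,
                                          drop = FALSE])
}
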