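#' The ACMG/AMP evidence-combining rule table
#'
#' Transcription of the published combining criteria (Richards et al. 2015)
#' as data: each row states the minimum number of evidence codes per
#' strength category (very strong PVS, strong PS, moderate PM, supporting
#' PP, stand-alone benign BA, strong benign BS, supporting benign BP)
#' needed to fire that rule. Shipping the table as a data file keeps rule
#' provenance auditable and the combiner free of hard-coded branching.
#'
#' @return `data.frame` with columns class, rule, pvs, ps, pm, pp, ba, bs, bp.
#' @export
acmg_rules <- function() {
  path <- system.file("extdata", "acmg_combining_rules.tsv", package = "rvburden")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

acmg_vocabulary <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

#' Combine ACMG evidence codes into a pathogenicity class
#'
#' Counts the supplied codes per strength category and fires every
#' combining rule whose minimum counts are met. The strongest fired class
#' wins within a direction; if both a pathogenic-direction and a
#' benign-direction rule fire, the evidence is contradictory and the call
#' is VUS. No rule fired is also VUS. PP5/BP6 (reputable source) are
#' retained in the vocabulary (they predate their later ClinGen
#' deprecation and remain in wide use).
#'
#' @param codes character vector of evidence codes, e.g.
#'   `c("PVS1", "PP1", "PP3", "PP5")`.
#' @param rules rule table, defaults to [acmg_rules()].
#' @return list with `class` (one of Pathogenic, Likely pathogenic, VUS,
#'   Likely benign, Benign) and `rule_fired` (first rule of the winning
#'   class, `NA` for VUS).
#' @export
combine_evidence <- function(codes, rules = acmg_rules()) {
  codes <- unique(as.character(codes))
  bad <- setdiff(codes, acmg_vocabulary())
  if (length(bad)) stop("unknown ACMG code(s): ", paste(bad, collapse = ", "))
  if ("BA1" %in% codes && "PVS1" %in% codes) {
    warning("BA1 and PVS1 supplied together: internally inconsistent evidence")
  }
  n <- c(pvs = sum(grepl("^PVS", codes)), ps = sum(grepl("^PS", codes)),
         pm = sum(grepl("^PM", codes)), pp = sum(grepl("^PP", codes)),
         ba = sum(grepl("^BA", codes)), bs = sum(grepl("^BS", codes)),
         bp = sum(grepl("^BP", codes)))
  fired <- vapply(seq_len(nrow(rules)), function(i) {
    all(n >= unlist(rules[i, c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")]))
  }, logical(1))
  classes <- rules$class[fired]
  path_dir <- intersect(c("Pathogenic", "Likely pathogenic"), classes)
  ben_dir <- intersect(c("Benign", "Likely benign"), classes)
  if (length(path_dir) && length(ben_dir)) {
    return(list(class = "VUS", rule_fired = NA_character_))
  }
  winner <- c(path_dir, ben_dir)
  if (!length(winner)) return(list(class = "VUS", rule_fired = NA_character_))
  cls <- winner[1]  # vectors above are ordered strongest-first
  list(class = cls, rule_fired = rules$rule[fired & rules$class == cls][1])
}

#' Classify variants from a JSON evidence file
#'
#' Input: JSON array of objects `{variant_id, codes: [..]}`. Output (when
#' `out` is given): array of `{variant_id, class, rule_fired}`.
#'
#' @param path input JSON path.
#' @param out optional output JSON path.
#' @return `data.frame` with variant_id, class, rule_fired.
#' @export
acmg_classify_json <- function(path, out = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  res <- do.call(rbind, lapply(recs, function(r) {
    v <- combine_evidence(unlist(r$codes))
    data.frame(variant_id = r$variant_id, class = v$class,
               rule_fired = v$rule_fired, stringsAsFactors = FALSE)
  }))
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, na = "null", pretty = TRUE)
  }
  res
}
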