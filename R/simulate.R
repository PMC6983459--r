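#' Simulation configuration for synthetic case-control cohorts
#'
#' Defaults mirror the study design the pipeline targets: 574 cases versus
#' 828 controls, a control carrier rate of qualifying variants of about
#' 1.7% (14 carriers in 828 at the observed scale), 4.8% of coding sites
#' with a case/control coverage imbalance beyond the pruning threshold,
#' and a two-component CADD score mixture straddling the D-mis cutoff of
#' 20 with roughly a third of qualifying missense variants above it
#' (11 of 30 at the observed scale).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_sites number of coding sites to simulate coverage for.
#' @param carrier_rate_controls per-subject probability of carrying a
#'   qualifying variant in the control population.
#' @param planted_or odds ratio of carriage in cases versus controls
#'   (1 = null).
#' @param frac_imbalanced_sites fraction of sites planted with a coverage
#'   difference beyond the pruning threshold (realized as an exact count).
#' @param cadd_mixture list with `weight_hi` (probability a missense score
#'   comes from the high component) and the two normal components
#'   (`mean_lo`, `sd_lo`, `mean_hi`, `sd_hi`).
#' @param consequence_probs named probabilities for missense /
#'   frameshift / splice_site consequences of qualifying variants
#'   (28/1/1 of 30 at the observed scale).
#' @param novelty_leak_rate probability a simulated variant has an entry
#'   in one of the novelty frequency resources (and is therefore removed
#'   by the novelty filter).
#' @param recurrence_rate probability a case variant is a doubleton
#'   (carried by a second case subject), emulating the recurrent-variant
#'   pattern; default 0 (all singletons).
#' @param seed RNG seed; all outputs are deterministic given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 574, n_controls = 828, n_sites = 1000,
                       carrier_rate_controls = 14 / 828, planted_or = 1,
                       frac_imbalanced_sites = 0.048,
                       cadd_mixture = list(weight_hi = 11 / 30, mean_lo = 12,
                                           sd_lo = 4, mean_hi = 28, sd_hi = 5),
                       consequence_probs = c(missense = 28 / 30,
                                             frameshift = 1 / 30,
                                             splice_site = 1 / 30),
                       novelty_leak_rate = 0.1, recurrence_rate = 0,
                       seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("cohort sizes must be >= 1")
  if (carrier_rate_controls <= 0 || carrier_rate_controls >= 1) {
    stop("carrier_rate_controls must lie in (0,1)")
  }
  if (planted_or <= 0) stop("planted_or must be positive")
  p1 <- case_carrier_prob(carrier_rate_controls, planted_or)
  if (p1 >= 1) stop("planted odds imply an impossible case carrier probability")
  probs <- c(frac_imbalanced_sites, novelty_leak_rate, recurrence_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_sites = as.integer(n_sites),
                 carrier_rate_controls = carrier_rate_controls,
                 planted_or = planted_or,
                 frac_imbalanced_sites = frac_imbalanced_sites,
                 cadd_mixture = cadd_mixture,
                 consequence_probs = consequence_probs,
                 novelty_leak_rate = novelty_leak_rate,
                 recurrence_rate = recurrence_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# carrier probability in cases implied by the planted odds ratio
case_carrier_prob <- function(p0, or) {
  odds1 <- or * p0 / (1 - p0)
  odds1 / (1 + odds1)
}

#' Draw collapsed carrier counts under the planted model
#'
#' Lightweight counts-only simulator used for type-I-error and power
#' studies: case carriage is Bernoulli with odds `planted_or` times the
#' control odds.
#'
#' @param config a `sim_config`.
#' @return a `collapsed_counts`.
#' @export
simulate_burden_counts <- function(config) {
  p0 <- config$carrier_rate_controls
  p1 <- case_carrier_prob(p0, config$planted_or)
  collapsed_counts(stats::rbinom(1, config$n_cases, p1), config$n_cases,
                   stats::rbinom(1, config$n_controls, p0), config$n_controls)
}

#' Generate a complete synthetic study dataset
#'
#' Produces, deterministically under the config seed, every input the
#' pipeline consumes: a qualifying-variant table with CADD scores and
#' consequences, heterozygous singleton carrier genotypes with the planted
#' case/control odds ratio, a coverage-site table with an exact planted
#' count of imbalanced sites, per-resource frequency tables realizing the
#' novelty leak rate, and a three-generation pedigree carrying one planted
#' fully penetrant dominant LGD variant plus a non-segregating decoy.
#' Qualifying variants are placed on coverage-balanced sites so the
#' planted association survives harmonization by construction.
#'
#' @param config a `sim_config`.
#' @return list of class `synthetic_dataset` with elements `variants`,
#'   `carriers`, `cohorts`, `coverage`, `pedigree`, `family_variants`,
#'   `family_genotypes` and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  thr <- 0.10  # pruning threshold the imbalanced sites are planted beyond

  # ---- coverage: exact planted count of imbalanced sites
  n_imb <- round(config$frac_imbalanced_sites * config$n_sites)
  pos <- sort(sample.int(2e6, config$n_sites)) + 48e6L
  imb <- sample.int(config$n_sites, n_imb)
  base <- stats::runif(config$n_sites, 0.85, 1)
  diff <- stats::runif(config$n_sites, 0, thr)
  diff[imb] <- stats::runif(n_imb, thr + 0.01, 0.4)
  sgn <- sample(c(-1, 1), config$n_sites, replace = TRUE)
  fc <- pmin(1, pmax(0, base + sgn * diff / 2))
  ft <- pmin(1, pmax(0, base - sgn * diff / 2))
  # keep the realized |difference| on the intended side of the threshold
  # even after clamping to [0,1]
  clamped <- abs(fc - ft) != diff
  fc[clamped] <- pmin(1, diff[clamped])
  ft[clamped] <- 0
  coverage <- coverage_sites("15", pos, round(fc, 4), round(ft, 4))

  # ---- cohorts and carrier draws under the planted odds ratio
  p0 <- config$carrier_rate_controls
  p1 <- case_carrier_prob(p0, config$planted_or)
  subjects <- data.frame(
    subject_id = c(sprintf("CASE%04d", seq_len(config$n_cases)),
                   sprintf("CTRL%04d", seq_len(config$n_controls))),
    cohort = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    stringsAsFactors = FALSE
  )
  carrier_flag <- stats::rbinom(nrow(subjects), 1,
                                ifelse(subjects$cohort == "case", p1, p0)) == 1
  carrier_subj <- subjects$subject_id[carrier_flag]
  n_var <- length(carrier_subj)

  balanced_sites <- setdiff(seq_len(config$n_sites), imb)
  site_idx <- sample(balanced_sites, n_var, replace = FALSE)
  cons <- sample(names(config$consequence_probs), n_var, replace = TRUE,
                 prob = config$consequence_probs)
  mx <- config$cadd_mixture
  hi <- stats::runif(n_var) < mx$weight_hi
  cadd <- round(pmax(0, ifelse(hi, stats::rnorm(n_var, mx$mean_hi, mx$sd_hi),
                               stats::rnorm(n_var, mx$mean_lo, mx$sd_lo))), 1)
  ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  variants <- variant_table(
    chrom = "15", pos = coverage$pos[site_idx], ref = ref, alt = alt,
    gene = "GENE1", consequence = cons, cadd = cadd,
    variant_id = sprintf("SV%04d", seq_len(n_var)),
    protein_pos = pmax(1L, as.integer(seq_len(n_var) * 7L)),
    af = list(`1KG` = NA_real_, ESP = NA_real_, ExAC = NA_real_,
              dbSNP = NA_real_, UMD = NA_real_, gnomAD = NA_real_)
  )
  # novelty leak: some variants surface in a random novelty resource
  leak <- stats::runif(n_var) < config$novelty_leak_rate
  res_pick <- sample(c("1KG", "ESP", "ExAC", "dbSNP", "UMD"), n_var, replace = TRUE)
  for (i in which(leak)) {
    variants[[paste0("af_", res_pick[i])]][i] <- signif(stats::runif(1, 1e-5, 1e-3), 3)
  }
  carriers <- data.frame(subject_id = carrier_subj,
                         variant_id = variants$variant_id,
                         stringsAsFactors = FALSE)
  # optional doubletons in cases (recurrent-variant pattern)
  if (config$recurrence_rate > 0) {
    case_vars <- which(carrier_subj %in% subjects$subject_id[subjects$cohort == "case"])
    dup <- case_vars[stats::runif(length(case_vars)) < config$recurrence_rate]
    if (length(dup)) {
      extra_subj <- sample(setdiff(subjects$subject_id[subjects$cohort == "case"],
                                   carrier_subj), length(dup))
      carriers <- rbind(carriers, data.frame(subject_id = extra_subj,
                                             variant_id = variants$variant_id[dup]))
    }
  }

  fam <- planted_family()

  truth <- list(
    planted_or = config$planted_or,
    carrier_rate_controls = p0, carrier_rate_cases = p1,
    n_cases = config$n_cases, n_controls = config$n_controls,
    n_variants = n_var,
    n_case_carriers = sum(carrier_subj %in% subjects$subject_id[subjects$cohort == "case"]),
    n_control_carriers = sum(carrier_subj %in% subjects$subject_id[subjects$cohort == "control"]),
    n_imbalanced_sites = n_imb, n_sites = config$n_sites,
    n_novelty_leaked = sum(leak),
    planted_family_variant = "FAMVAR1",
    seed = config$seed
  )
  structure(list(variants = variants, carriers = carriers, cohorts = subjects,
                 coverage = coverage, pedigree = fam$ped,
                 family_variants = fam$variants, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

# three-generation pedigree with a fully penetrant dominant LGD variant
# (FAMVAR1) and a decoy missense carried by an unaffected member
planted_family <- function() {
  members <- data.frame(
    id = c("I-1", "I-2", "II-1", "II-2", "III-1"),
    father_id = c(NA, NA, NA, "I-1", "II-1"),
    mother_id = c(NA, NA, NA, "I-2", "II-2"),
    sex = c(1, 2, 1, 2, 1),
    affected = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  genotypes <- rbind(
    data.frame(id = c("II-1", "II-2", "III-1"), variant_id = "FAMVAR1",
               state = c("non-carrier", "carrier", "carrier")),
    data.frame(id = c("II-1", "II-2", "III-1"), variant_id = "FAMVAR2",
               state = c("carrier", "non-carrier", "carrier"))
  )
  variants <- variant_table(
    chrom = "15", pos = c(48787348L, 48790001L), ref = c("C", "G"),
    alt = c("T", "A"), gene = "GENE1",
    consequence = c("nonsense", "missense"), cadd = c(42, 25),
    variant_id = c("FAMVAR1", "FAMVAR2"),
    protein_change = c("p.Trp883Ter", "p.Ala900Val")
  )
  list(ped = pedigree(members, genotypes, proband = "III-1"), variants = variants)
}

#' Write a synthetic dataset to disk
#'
#' Emits every file the pipeline readers consume: a VCF v4.2 with GT-only
#' heterozygous calls across all subjects, cohort / coverage / frequency
#' TSVs, a 6-column PED with a genotype-state sidecar, a truth JSON, and a
#' manifest with MD5 checksums.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return invisible manifest `data.frame` (file, md5).
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)

  write_carrier_vcf(dataset$variants, dataset$carriers,
                    dataset$cohorts$subject_id, p("variants.vcf"))
  paths <- c(paths, p("variants.vcf"))
  utils::write.table(dataset$cohorts, p("cohorts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("cohorts.tsv"))
  utils::write.table(dataset$carriers, p("carriers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("carriers.tsv"))
  write_coverage_tsv(dataset$coverage, p("coverage.tsv"))
  paths <- c(paths, p("coverage.tsv"))
  for (res in c("1KG", "ESP", "ExAC", "dbSNP", "UMD", "gnomAD")) {
    col <- paste0("af_", res)
    tab <- dataset$variants[!is.na(dataset$variants[[col]]),
                            c("variant_id", col), drop = FALSE]
    names(tab) <- c("variant_id", "af")
    f <- p(paste0("af_", res, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  utils::write.table(as.data.frame(dataset$variants), p("variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("variants.tsv"))
  ped <- dataset$pedigree
  ped_tab <- data.frame(family_id = "FAM1", id = ped$members$id,
                        father_id = ifelse(is.na(ped$members$father_id), "0", ped$members$father_id),
                        mother_id = ifelse(is.na(ped$members$mother_id), "0", ped$members$mother_id),
                        sex = ped$members$sex,
                        phenotype = ifelse(ped$members$affected, 2, 1))
  utils::write.table(ped_tab, p("family.ped"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p("family.ped"))
  utils::write.table(ped$genotypes, p("family_genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("family_genotypes.tsv"))
  utils::write.table(as.data.frame(dataset$family_variants), p("family_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("family_variants.tsv"))
  jsonlite::write_json(dataset$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p("truth.json"))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

# minimal VCF v4.2 emission: GT-only heterozygous carrier calls
write_carrier_vcf <- function(variants, carriers, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD deleteriousness score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  o <- order(variants$chrom, variants$pos)
  for (i in o) {
    gt <- rep("0/0", length(sample_ids))
    gt[sample_ids %in% carriers$subject_id[carriers$variant_id == variants$variant_id[i]]] <- "0/1"
    info <- sprintf("GENE=%s;CSQ=%s%s", variants$gene[i], variants$consequence[i],
                    if (is.na(variants$cadd[i])) "" else sprintf(";CADD=%s", variants$cadd[i]))
    writeLines(paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
                       variants$ref[i], variants$alt[i], ".", "PASS", info,
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a written fixture back through the pipeline readers
#'
#' @param dir directory produced by [write_fixture()].
#' @return list with `variants`, `carriers`, `cohorts`, `coverage`,
#'   `pedigree`, `family_variants` and `truth`.
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  vcf <- read_variant_vcf(p("variants.vcf"))
  variants <- vcf$variants
  for (res in c("1KG", "ESP", "ExAC", "dbSNP", "UMD", "gnomAD")) {
    col <- paste0("af_", res)
    variants[[col]] <- NA_real_
    f <- p(paste0("af_", res, ".tsv"))
    if (file.exists(f)) {
      tab <- utils::read.delim(f, stringsAsFactors = FALSE)
      variants[[col]][match(tab$variant_id, variants$variant_id)] <- tab$af
    }
  }
  members <- read_ped(p("family.ped"))
  geno <- utils::read.delim(p("family_genotypes.tsv"), stringsAsFactors = FALSE)
  list(variants = variants,
       carriers = vcf$carriers,
       cohorts = utils::read.delim(p("cohorts.tsv"), stringsAsFactors = FALSE),
       coverage = read_coverage_tsv(p("coverage.tsv")),
       pedigree = pedigree(members[, c("id", "father_id", "mother_id", "sex", "affected")],
                           geno),
       family_variants = read_variant_tsv(p("family_variants.tsv")),
       truth = jsonlite::fromJSON(p("truth.json")))
}
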