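family_fixture <- function() {
  members <- data.frame(
    id = c("I-1", "I-2", "II-1", "II-2", "III-1"),
    father_id = c(NA, NA, NA, "I-1", "II-1"),
    mother_id = c(NA, NA, NA, "I-2", "II-2"),
    sex = c(1, 2, 1, 2, 1),
    affected = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  genotypes <- data.frame(
    id = c("II-1", "II-2", "III-1"),
    variant_id = "nonsense1",
    state = c("non-carrier", "carrier", "carrier")
  )
  pedigree(members, genotypes, proband = "III-1")
}

nonsense_variant <- function(id = "nonsense1", consequence = "nonsense", cadd = 42) {
  variant_table(chrom = "15", pos = 48787348, ref = "C", alt = "T", gene = "FBN1",
                consequence = consequence, cadd = cadd, variant_id = id,
                protein_change = "p.Trp883Ter")
}

test_that("a fully penetrant dominant variant cosegregates in the three-generation family", {
  ped <- family_fixture()
  verdict <- dominant_candidates(ped, nonsense_variant())
  expect_true(verdict$cosegregates)
  expect_equal(verdict$informative_members, 3L)
  expect_equal(verdict$violations, "")
})

test_that("an unaffected carrier or an affected non-carrier is a violation; missing genotypes are not", {
  ped <- family_fixture()
  ped$genotypes$state[ped$genotypes$id == "II-1"] <- "carrier"
  v <- dominant_candidates(ped, nonsense_variant())
  expect_false(v$cosegregates)
  expect_equal(v$violations, "II-1")
  # but a reduced-penetrance screen can tolerate it
  expect_true(dominant_candidates(ped, nonsense_variant(),
                                  tolerated_unaffected_carriers = 1)$cosegregates)

  ped2 <- family_fixture()
  ped2$genotypes$state[ped2$genotypes$id == "II-2"] <- "non-carrier"
  v2 <- dominant_candidates(ped2, nonsense_variant())
  expect_false(v2$cosegregates)
  expect_equal(v2$violations, "II-2")

  # only the proband genotyped: uninformative, never positive
  ped3 <- family_fixture()
  ped3$genotypes <- ped3$genotypes[ped3$genotypes$id == "III-1", ]
  v3 <- dominant_candidates(ped3, nonsense_variant())
  expect_false(v3$cosegregates)
  expect_equal(v3$informative_members, 1L)
  expect_equal(v3$violations, "")
})

test_that("an ungenotyped proband is an error and pedigree invariants hold", {
  ped <- family_fixture()
  ped$genotypes <- ped$genotypes[ped$genotypes$id != "III-1", ]
  expect_error(dominant_candidates(ped, nonsense_variant()), "not genotyped")
  members <- data.frame(id = "X", father_id = "GHOST", mother_id = NA,
                        sex = 1, affected = TRUE)
  expect_error(pedigree(members, data.frame(id = "X", variant_id = "v",
                                            state = "carrier")),
               "unresolved parental reference")
  members2 <- data.frame(id = "X", father_id = NA, mother_id = NA,
                         sex = 1, affected = FALSE)
  expect_error(pedigree(members2, data.frame(id = "X", variant_id = "v",
                                             state = "carrier")),
               "no affected member")
})

test_that("adding an unaffected carrier only ever shrinks the cosegregating set", {
  set.seed(31)
  for (rep in 1:10) {
    ped <- family_fixture()
    vars <- variant_table(chrom = "1", pos = 1:5, ref = "A", alt = "G", gene = "G",
                          consequence = "missense", cadd = runif(5, 10, 40),
                          variant_id = paste0("m", 1:5), protein_pos = 1:5)
    states <- expand.grid(id = ped$members$id, variant_id = vars$variant_id,
                          stringsAsFactors = FALSE)
    states$state <- ifelse(ped$members$affected[match(states$id, ped$members$id)],
                           "carrier",
                           sample(c("carrier", "non-carrier", "missing"),
                                  nrow(states), replace = TRUE))
    ped$genotypes <- states
    before <- dominant_candidates(ped, vars)
    # force one more unaffected member to carry a random variant
    pick <- sample(vars$variant_id, 1)
    ped2 <- ped
    sel <- ped2$genotypes$id == "II-1" & ped2$genotypes$variant_id == pick
    ped2$genotypes$state[sel] <- "carrier"
    after <- dominant_candidates(ped2, vars)
    expect_true(all(after$variant_id[after$cosegregates] %in%
                    before$variant_id[before$cosegregates]))
  }
})

test_that("a planted fully penetrant variant is recovered exactly when all members are genotyped", {
  ped <- family_fixture()
  vars <- rbind(nonsense_variant(),
                variant_table(chrom = "1", pos = 2:4, ref = "A", alt = "G",
                              gene = "G", consequence = "missense",
                              cadd = c(25, 30, 15), variant_id = paste0("m", 1:3),
                              protein_pos = 2:4))
  set.seed(8)
  extra <- expand.grid(id = ped$members$id, variant_id = paste0("m", 1:3),
                       stringsAsFactors = FALSE)
  # decoys: random states guaranteed to break cosegregation somewhere
  extra$state <- "non-carrier"
  extra$state[extra$id == "II-1"] <- "carrier"
  full_plant <- data.frame(id = ped$members$id, variant_id = "nonsense1",
                           state = ifelse(ped$members$affected, "carrier", "non-carrier"))
  ped$genotypes <- rbind(full_plant, extra)
  verdicts <- dominant_candidates(ped, vars)
  expect_equal(verdicts$variant_id[verdicts$cosegregates], "nonsense1")
})

test_that("ranking puts cosegregating LGD first, then damaging missense by descending CADD, stably", {
  ped <- family_fixture()
  vars <- rbind(nonsense_variant(),
                variant_table(chrom = "1", pos = 2:3, ref = "A", alt = "G",
                              gene = "G", consequence = "missense",
                              cadd = c(21, 25), variant_id = c("mis21", "mis25"),
                              protein_pos = 2:3))
  ped$genotypes <- do.call(rbind, lapply(vars$variant_id, function(vid) {
    data.frame(id = ped$members$id, variant_id = vid,
               state = ifelse(ped$members$affected, "carrier", "non-carrier"))
  }))
  verdicts <- dominant_candidates(ped, vars)
  ranked <- rank_candidates(verdicts, classify_variants(vars))
  expect_equal(ranked$variant_id, c("nonsense1", "mis25", "mis21"))
  expect_equal(rank_candidates(verdicts[0, ], vars), verdicts[0, ])
})
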