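test_that("templates build valid pedigrees with the expected structure", {
  ped <- build_pedigree("first_cousin")
  expect_s3_class(ped, "pedigree")
  # one shared grandparental couple; the affected child's parents are
  # first cousins (their fathers/mothers are siblings)
  expect_setequal(founders(ped), c("GP_F", "GP_M", "U1_SP", "U2_SP"))
  fa <- ped[ped$id == "FA", ]; mo <- ped[ped$id == "MO", ]
  gp_of <- function(row) {
    par <- c(row$father, row$mother)
    unique(na.omit(unlist(ped[match(par, ped$id), c("father", "mother")])))
  }
  expect_length(intersect(gp_of(fa), gp_of(mo)), 2)  # shared grandparents
  expect_equal(affected_ids(ped), "P1")

  ped2 <- build_pedigree("double_first_cousin")
  expect_equal(sum(is.na(ped2$father)), 4 + 0)  # two founder couples only

  ped3 <- build_pedigree("two_family_founder")
  expect_setequal(affected_ids(ped3), c("F1_P1", "F2_P1"))
  expect_true(all(c("ANC_F", "ANC_M") %in% founders(ped3)))
  carrier <- attr(ped3, "carrier")
  expect_equal(carrier$hap, "ANC_F.1")
  # founder allele reaches both parents of each affected child
  expect_true(all(c("F1_P1", "F2_P1") %in% carrier$chain$child))
})

test_that("custom pedigrees violating invariants are rejected by name", {
  base <- data.frame(id = c("A", "B", "C"), father = c(NA, NA, "A"),
                     mother = c(NA, NA, "B"), sex = c("male", "female", "male"),
                     affected = c(FALSE, FALSE, TRUE))
  expect_s3_class(build_pedigree("custom", members = base), "pedigree")

  own_father <- transform(base, father = c(NA, NA, "C"))
  expect_error(build_pedigree("custom", members = own_father), "own parent")

  half <- transform(base, mother = c(NA, NA, NA))
  expect_error(build_pedigree("custom", members = half), "both")

  dangling <- transform(base, father = c(NA, NA, "X"))
  expect_error(build_pedigree("custom", members = dangling), "X")

  wrong_sex <- transform(base, sex = c("female", "female", "male"))
  expect_error(build_pedigree("custom", members = wrong_sex), "not male")

  cyc <- data.frame(id = c("A", "B", "C", "D"),
                    father = c(NA, NA, "A", "C"),
                    mother = c(NA, NA, "D", "B"),
                    sex = c("male", "female", "male", "female"),
                    affected = FALSE)
  expect_error(build_pedigree("custom", members = cyc), "cycle")

  expect_error(build_pedigree("custom"), "members")
})

test_that("inbreeding coefficient matches closed forms and founders are 0", {
  ped <- build_pedigree("first_cousin")
  expect_identical(inbreeding_coefficient(ped, "P1"), 1 / 16)
  for (f in founders(ped)) expect_identical(inbreeding_coefficient(ped, f), 0)
  expect_identical(inbreeding_coefficient(ped, "FA"), 0)  # parents unrelated

  ped2 <- build_pedigree("double_first_cousin")
  expect_identical(inbreeding_coefficient(ped2, "P1"), 1 / 8)

  ped3 <- build_pedigree("two_family_founder")
  expect_identical(inbreeding_coefficient(ped3, "F1_P1"), 1 / 16)
  expect_identical(inbreeding_coefficient(ped3, "F2_P1"), 1 / 8)

  expect_error(inbreeding_coefficient(ped, "nobody"), "unknown individual")
})

test_that("path counting agrees with the recursive-kinship oracle", {
  # all members of all templates, plus a deeper ad-hoc inbred pedigree
  for (tmpl in c("first_cousin", "double_first_cousin", "two_family_founder")) {
    ped <- build_pedigree(tmpl)
    for (id in ped$id)
      expect_equal(inbreeding_coefficient(ped, id), inbreeding_oracle(ped, id),
                   info = paste(tmpl, id))
  }
  # child of half-sibs whose shared father is himself inbred (F = 1/4):
  # F(child) = (1/2)^3 * (1 + 1/4) = 5/32
  ped <- validate_pedigree(data.frame(
    id = c("G1", "G2", "S1", "S2", "F", "M1", "M2", "A", "B", "C"),
    father = c(NA, NA, "G1", "G1", "S1", NA, NA, "F", "F", "A"),
    mother = c(NA, NA, "G2", "G2", "S2", NA, NA, "M1", "M2", "B"),
    sex = c("male", "female", "male", "female", "male", "female", "female",
            "male", "female", "male"),
    affected = FALSE))
  expect_identical(inbreeding_coefficient(ped, "F"), 1 / 4)
  expect_identical(inbreeding_coefficient(ped, "C"), (1 / 2)^3 * (1 + 1 / 4))
  expect_equal(inbreeding_coefficient(ped, "C"), inbreeding_oracle(ped, "C"))
})

test_that("pedigree PED round-trips", {
  ped <- build_pedigree("two_family_founder")
  path <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  cols <- c("id", "father", "mother", "sex", "affected", "family")
  expect_identical(as.data.frame(ped2)[cols], as.data.frame(ped)[cols])
})
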