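test_that("tabular relatedness reproduces the classical coefficients", {
  ped <- data.frame(
    id   = c("M", "F", "C1", "C2", "HS", "GC"),
    dam  = c(NA, NA, "F", "F", "F", "C1"),
    sire = c(NA, NA, "M", "M", "X", "Y"),
    stringsAsFactors = FALSE)
  A <- relatedness_matrix(ped)
  expect_equal(relatedness(A, "M", "C1"), 0.5)     # parent-offspring
  expect_equal(relatedness(A, "M", "F"), 0)        # founders
  expect_equal(relatedness(A, "C1", "C2"), 0.5)    # full siblings
  expect_equal(relatedness(A, "C1", "HS"), 0.25)   # half siblings
  expect_equal(relatedness(A, "F", "GC"), 0.25)    # grandparent-grandchild
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 1))
})

test_that("relatedness matches the path-counting oracle on random pedigrees", {
  set.seed(99)
  for (rep in 1:8) {
    ped <- random_noninbred_pedigree(n_founders = 6, n_generations = 3,
                                     per_generation = 4)
    A <- relatedness_matrix(ped)
    ids <- ped$id
    pick <- t(combn(sample(ids, min(8, length(ids))), 2))
    for (k in seq_len(nrow(pick))) {
      i <- pick[k, 1]; j <- pick[k, 2]
      expect_equal(A[i, j], path_counting_r(ped, i, j),
                   tolerance = 1e-12,
                   label = paste("pair", i, j, "rep", rep))
    }
  }
})

test_that("pedigree cycles are rejected", {
  ped <- data.frame(id = c("A", "B"), dam = c("B", "A"),
                    sire = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(relatedness_matrix(ped), "cycle")
})

test_that("related-group classification uses the dominants and an inclusive threshold", {
  ped <- data.frame(
    id   = c("MUM", "IMM", "CALLER", "HS", "X1"),
    dam  = c(NA, NA, "MUM", "MUM", NA),
    sire = c(NA, NA, "DAD", "OTHER", NA),
    stringsAsFactors = FALSE)
  A <- relatedness_matrix(ped)
  ind <- make_individuals(
    list("MUM", "female", "2004-01-01", "N", "dominant"),
    list("IMM", "male", "2004-01-01", "N", "dominant"),
    list("CALLER", "male", "2008-01-01", "F", "subordinate"),
    list("HS", "female", "2008-06-01", "H", "dominant"),
    list("X1", "male", "2004-01-01", "U", "dominant"))
  expect_true(is_related_group("CALLER", "N", ind, A))    # mother, r = 0.5
  expect_false(is_related_group("CALLER", "U", ind, A))   # founder
  expect_true(is_related_group("CALLER", "H", ind, A))    # half-sib r = 0.25
  expect_error(is_related_group("CALLER", "NOPE", ind, A), "NOPE")
})

test_that("neighbour profiles count adults, partners and same-sex unrelated adults", {
  ref <- as.Date("2011-01-15")
  ped <- data.frame(
    id   = c("DF", "DM", "CALLER", "SIB1", "SIB2"),
    dam  = c(NA, NA, "DF", "DF", "DF"),
    sire = c(NA, NA, "DM", "DM", "DM"),
    stringsAsFactors = FALSE)
  A <- relatedness_matrix(ped)

  # empty neighbour group
  ind0 <- make_individuals(
    list("CALLER", "male", "2008-01-01", "F", "subordinate"))
  p0 <- profile_neighbour("CALLER", "EMPTY", ind0, A, ref)
  expect_equal(p0$n_adults, 0)
  expect_equal(p0$n_potential_partners, 0)

  # neighbour of full siblings only -> no partners
  ind1 <- make_individuals(
    list("CALLER", "male", "2008-01-01", "F", "subordinate"),
    list("SIB1", "female", "2008-01-01", "N", "dominant"),
    list("SIB2", "female", "2008-06-01", "N", "subordinate"))
  p1 <- profile_neighbour("CALLER", "N", ind1, A, ref)
  expect_equal(p1$n_potential_partners, 0)
  expect_true(p1$related)

  # mixed group for a male caller: 2 unrelated adult females + 1 related
  # adult female + 1 unrelated juvenile female + 1 unrelated adult male
  ind2 <- make_individuals(
    list("CALLER", "male", "2008-01-01", "F", "subordinate"),
    list("UF1", "female", "2005-01-01", "M", "dominant"),
    list("UF2", "female", "2006-01-01", "M", "subordinate"),
    list("SIB1", "female", "2008-01-01", "M", "subordinate"),
    list("JUV", "female", "2010-09-01", "M", "subordinate"),
    list("UM1", "male", "2005-01-01", "M", "dominant"))
  p2 <- profile_neighbour("CALLER", "M", ind2, A, ref)
  expect_equal(p2$n_adults, 4)
  expect_equal(p2$n_potential_partners, 2)
  expect_equal(p2$n_same_sex_unrelated_adults, 1)

  # adult threshold is inclusive at exactly 365 days
  ind3 <- make_individuals(
    list("CALLER", "male", "2008-01-01", "F", "subordinate"),
    list("YF", "female", format(ref - 365), "M", "subordinate"))
  p3 <- profile_neighbour("CALLER", "M", ind3, A, ref)
  expect_equal(p3$n_adults, 1)

  expect_error(profile_neighbour("NOSEX", "M", make_individuals(
    list("NOSEX", "unknown", "2008-01-01", "F", "subordinate")), A, ref),
    "unknown sex")
})

test_that("partner counts are monotone in adding an unrelated opposite-sex adult", {
  ref <- as.Date("2011-01-15")
  ped <- data.frame(id = "CALLER", dam = NA_character_,
                    sire = NA_character_, stringsAsFactors = FALSE)
  A <- relatedness_matrix(ped)
  set.seed(3)
  ind <- make_individuals(
    list("CALLER", "male", "2008-01-01", "F", "subordinate"),
    list("N1", "female", "2005-01-01", "N", "dominant"))
  for (k in 1:5) {
    before <- profile_neighbour("CALLER", "N", ind, A, ref)$n_potential_partners
    ind <- rbind(ind, make_individuals(
      list(paste0("ADD", k), "female", "2006-01-01", "N", "subordinate")))
    after <- profile_neighbour("CALLER", "N", ind, A, ref)$n_potential_partners
    expect_equal(after, before + 1)
  }
})
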