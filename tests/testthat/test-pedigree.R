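test_that("the three printed breeding designs yield 12, 30 and 28 families", {
  expect_equal(cross_design(12, 5, "nested")$n_families, 12)
  expect_equal(
    cross_design(15, 10, "partial_factorial",
      dams_per_sire = 3, sires_per_dam = 2
    )$n_families,
    30
  )
  ir <- cross_design(20, 10, "split_egg_lot", n_split_dams = 8)
  expect_equal(ir$n_families, 28)
  # every sire kept within 2-3 dams, 8 dams split between 2 sires
  per_sire <- table(ir$matings$sire)
  expect_true(all(per_sire >= 2 & per_sire <= 3))
  expect_equal(sum(table(ir$matings$dam) == 2), 8)
})

test_that("design rules are enforced and infeasible rules are reported", {
  d <- cross_design(1, 1, "nested", dams_per_sire = c(1, 1))
  expect_equal(d$n_families, 1)
  # 5 sires x 3 dams each needs 15 dams, not 12-with-reuse
  expect_error(
    cross_design(12, 5, "partial_factorial", dams_per_sire = 3, sires_per_dam = 1),
    class = "morphherit_infeasible_design"
  )
  expect_error(
    cross_design(20, 5, "nested"),
    class = "morphherit_infeasible_design"
  )
  # matings unique, all parents used
  for (d in default_designs()) {
    m <- d$matings
    expect_equal(anyDuplicated(m[c("sire", "dam")]), 0L)
    expect_equal(length(unique(m$sire)), d$n_sires)
    expect_equal(length(unique(m$dam)), d$n_dams)
  }
})

test_that("pedigree expansion puts founders first with correct counts", {
  d <- cross_design(15, 10, "partial_factorial", dams_per_sire = 3, sires_per_dam = 2)
  ped <- pedigree_from_design(d, 8)
  expect_equal(nrow(ped), 25 + 240)
  expect_equal(sum(is.na(ped$sire)), 25)
  # parents precede offspring
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  off <- dplyr::filter(ped, !is.na(sire))
  expect_true(all(pos[off$sire] < pos[off$id]))
  expect_true(all(pos[off$dam] < pos[off$id]))
  # one-family, one-offspring design -> 3 records
  expect_equal(nrow(pedigree_from_design(cross_design(1, 1, "nested", dams_per_sire = c(1, 1)), 1)), 3)
})

test_that("relationship matrix reproduces textbook identities", {
  ped <- tibble::tibble(
    id = c("s", "d", "x", "o1", "o2"),
    sire = c(NA, NA, NA, "s", "s"),
    dam = c(NA, NA, NA, "d", "x")
  )
  A <- additive_relationship(ped)
  expect_equal(A["s", "o1"], 0.5) # parent-offspring
  expect_equal(A["o1", "o2"], 0.25) # paternal half sibs
  expect_equal(unname(diag(A)), rep(1, 5))
  # offspring of a full-sib mating: diagonal 1.25 (checked against the
  # coancestry-recursion oracle)
  ped2 <- tibble::tibble(
    id = c("s", "d", "a", "b", "i"),
    sire = c(NA, NA, "s", "s", "a"),
    dam = c(NA, NA, "d", "d", "b")
  )
  A2 <- additive_relationship(ped2)
  expect_equal(A2["i", "i"], 1.25)
  expect_equal(A2, kinship_oracle(ped2))
})

test_that("two-generation designs give exact full/half/zero relationships", {
  for (d in default_designs()) {
    ped <- pedigree_from_design(d, 2)
    A <- additive_relationship(ped)
    off <- dplyr::filter(ped, !is.na(family))
    for (i in 1:20) {
      pair <- sample(seq_len(nrow(off)), 2)
      a <- off[pair[1], ]
      b <- off[pair[2], ]
      expected <- 0.25 * (a$sire == b$sire) + 0.25 * (a$dam == b$dam)
      expect_equal(A[a$id, b$id], unname(expected))
    }
  }
})

test_that("tabular method agrees with the coancestry oracle on random pedigrees", {
  for (seed in 1:12) {
    ped <- random_pedigree(15, seed)
    A <- additive_relationship(ped)
    expect_equal(A, kinship_oracle(ped), tolerance = 1e-12)
    expect_equal(A, t(A))
    expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10)
    expect_true(all(A >= 0 & A <= 2))
    expect_true(all(diag(A) >= 1))
  }
})

test_that("pedigree errors name the offending label", {
  bad <- tibble::tibble(id = c("a", "b"), sire = c(NA, "zz"), dam = c(NA, NA))
  expect_error(additive_relationship(bad), "zz")
  unordered <- tibble::tibble(id = c("o", "s"), sire = c("s", NA), dam = c(NA, NA))
  expect_error(additive_relationship(unordered), "topologically")
})

test_that("pedigree CSV round-trips including unknown parents", {
  ped <- pedigree_from_design(cross_design(4, 2, "nested"), 3, strain = "st")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(as.data.frame(back), as.data.frame(ped))
})
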