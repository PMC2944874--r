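test_that("breeding values honour the pedigree covariance structure", {
  ap <- assinica_pedigree(2)
  expect_equal(unname(simulate_breeding_values(ap$A, 0, seed = 1)), rep(0, nrow(ap$A)))
  expect_error(simulate_breeding_values(ap$A, -1, 1), "non-negative")
  # determinism
  expect_identical(
    simulate_breeding_values(ap$A, 0.5, seed = 7),
    simulate_breeding_values(ap$A, 0.5, seed = 7)
  )
  # Monte-Carlo: half-sib covariance ~ 0.25 V_a, full-sib ~ 0.5 V_a
  off <- dplyr::filter(ap$ped, !is.na(family))
  hs <- which(outer(off$sire, off$sire, "==") & outer(off$dam, off$dam, "!="),
    arr.ind = TRUE
  )[1, ]
  fs <- which(outer(off$family, off$family, "==") & outer(off$id, off$id, "!="),
    arr.ind = TRUE
  )[1, ]
  draws <- vapply(1:600, function(s) {
    bv <- simulate_breeding_values(ap$A, 1, seed = 1000 + s)
    bv[off$id][c(hs[1], hs[2], fs[1], fs[2])]
  }, numeric(4))
  expect_lt(abs(cov(draws[1, ], draws[2, ]) - 0.25), 0.12)
  expect_lt(abs(cov(draws[3, ], draws[4, ]) - 0.5), 0.15)
})

test_that("a zero-variance study collapses to similarity transforms of the template", {
  p <- sim_params(
    shape_vc = list(c(V_a = 0, V_m = 0, V_c = 0, V_e = 0)),
    landmark_noise_sd = 0,
    strain_shape_shift = c(siskiwit = 0, assinica = 0, iron_river = 0),
    period_drift = c(0, 0, 0),
    n_per_family = c(2L, 2L, 2L)
  )
  st <- simulate_study(p, seed = 5)
  lmk1 <- dplyr::filter(st$landmarks, period == 1) |> dplyr::select(-period)
  fit <- gpa(lmk1)
  expect_lt(procrustes_ss_of(fit), 1e-12)
})

test_that("nuisance transforms do not move relative warp scores", {
  base_args <- list(
    n_per_family = c(3L, 3L, 3L),
    designs = list(assinica = cross_design(6, 4, "partial_factorial",
      dams_per_sire = 3, sires_per_dam = 2
    )),
    strain_shape_shift = c(assinica = 0),
    periods = 1L
  )
  p_on <- do.call(sim_params, base_args)
  p_off <- do.call(sim_params, c(base_args, list(
    rotation_range = c(0, 0), translation_range = c(0, 0), scale_range = c(1, 1)
  )))
  s_on <- simulate_study(p_on, seed = 8)
  s_off <- simulate_study(p_off, seed = 8)
  w_on <- relative_warps(dplyr::select(dplyr::filter(s_on$landmarks, period == 1), -period))
  w_off <- relative_warps(dplyr::select(dplyr::filter(s_off$landmarks, period == 1), -period))
  keep <- which(w_on$variance_fraction > 1e-9)
  delta <- as.matrix(w_on$relative[keep + 1]) - as.matrix(w_off$relative[keep + 1])
  expect_lt(max(abs(delta)), 1e-6)
})

test_that("the default study has 70 families and truth heritabilities are exact ratios", {
  p <- sim_params(n_per_family = c(1L, 1L, 1L))
  st <- simulate_study(p, seed = 3)
  expect_equal(length(unique(na.omit(st$pedigree$family))), 70)
  expect_equal(
    unname(st$truth$expected_h2_shape),
    vapply(p$shape_vc, function(vc) vc[["V_a"]] / sum(vc), 0)
  )
  expect_equal(st$truth$expected_h2_length, 25 / 50)
  # phenotypes positive and complete
  expect_true(all(st$phenotypes$length > 0))
  expect_true(all(st$phenotypes$weight > 0))
  expect_true(all(st$phenotypes$id %in% unique(st$landmarks$id)))
})

test_that("fixture trees are byte-identical across runs with the same seed", {
  p <- sim_params(n_per_family = c(2L, 1L, 1L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_study(p, d1, seed = 11)
  write_fixture_study(p, d2, seed = 11)
  files <- list.files(d1)
  expect_setequal(files, c(
    "landmarks_period1.tps", "landmarks_period2.tps", "landmarks_period3.tps",
    "pedigree.csv", "phenotypes.csv", "dam_traits.csv", "truth.json"
  ))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and the files round-trip through the readers
  ped <- read_pedigree(file.path(d1, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(additive_relationship(ped)))
  lmk <- read_tps(file.path(d1, "landmarks_period1.tps"))
  expect_equal(sum(lmk$landmark == 1), 140) # 70 families x 2 fish
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(shape_vc = list(c(V_a = -1, V_m = 0, V_c = 0, V_e = 1))), "non-negative")
  bad_basis <- list(matrix(1, 13, 2))
  expect_error(sim_params(effect_basis = bad_basis), "orthonormal|centered")
})
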