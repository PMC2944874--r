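test_that("centroid size: unit square value, homogeneity, rigid invariance", {
  sq <- tibble::tibble(id = "sq", landmark = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(centroid_size(sq)$csize, sqrt(2))
  lmk <- random_landmarks(5, seed = 11)
  cs <- centroid_size(lmk)$csize
  scaled <- dplyr::mutate(lmk, x = 3.7 * x, y = 3.7 * y)
  expect_equal(centroid_size(scaled)$csize, 3.7 * cs)
  rot <- dplyr::mutate(lmk, x0 = x, x = -y, y = x0)[, c("id", "landmark", "x", "y")]
  expect_equal(centroid_size(rot)$csize, cs)
  degen <- tibble::tibble(id = "d", landmark = 1:4, x = rep(1, 4), y = rep(2, 4))
  expect_error(centroid_size(degen), "degenerate")
})

test_that("GPA exactly superimposes similarity-transformed copies of one shape", {
  one <- random_landmarks(1, sd = 0.03, seed = 5)
  copies <- purrr::map_dfr(1:8, function(i) dplyr::mutate(one, id = paste0("c", i)))
  copies <- apply_similarity(copies, seed = 6)
  fit <- gpa(copies)
  expect_true(fit$converged)
  spread <- apply(fit$aligned, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)
  expect_lt(procrustes_ss_of(fit), 1e-14)
})

test_that("GPA consensus is the normalized mean and equidistant for two shapes", {
  lmk <- random_landmarks(20, seed = 7)
  fit <- gpa(lmk)
  mean_aligned <- apply(fit$aligned, c(1, 2), mean)
  expect_equal(
    unname(mean_aligned / sqrt(sum(mean_aligned^2))), fit$consensus,
    tolerance = 1e-8
  )
  two <- gpa(random_landmarks(2, sd = 0.05, seed = 8))
  d1 <- sum((two$aligned[, , 1] - two$consensus)^2)
  d2 <- sum((two$aligned[, , 2] - two$consensus)^2)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("bending energy has k - 3 nonzero eigenvalues and kills affine maps", {
  fit <- gpa(random_landmarks(10, seed = 9))
  wb <- warp_basis(fit$consensus)
  k <- nrow(fit$consensus)
  expect_equal(length(wb$eigenvalues), k - 3) # 10 for k = 13
  expect_equal(wb$bending_energy, t(wb$bending_energy))
  ev_all <- eigen(wb$bending_energy, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev_all) > -1e-10)
  # affine transform of the consensus has zero bending energy
  B <- matrix(c(1.2, 0.3, -0.1, 0.8), 2)
  aff <- wb$consensus %*% t(B)
  expect_lt(max(abs(t(aff) %*% wb$bending_energy %*% aff)), 1e-9)
  # principal warps orthonormal and orthogonal to the uniform basis
  expect_equal(crossprod(wb$principal_warps), diag(k - 3), tolerance = 1e-10)
  pw_vec <- rbind(wb$principal_warps, 0 * wb$principal_warps)
  expect_lt(max(abs(crossprod(wb$uniform_basis, pw_vec))), 1e-10)
  expect_error(
    warp_basis(cbind(1:13, 2 * (1:13))), # collinear landmarks
    "singular|degenerate"
  )
})

test_that("13 landmarks give 22 warp axes with variance fractions summing to 1", {
  ws <- relative_warps(random_landmarks(40, seed = 10))
  expect_equal(ws$n_axes, 22)
  expect_equal(ncol(ws$partial) - 1L, 22L)
  expect_equal(sum(ws$variance_fraction), 1)
  # relative warp axes mutually uncorrelated
  R <- as.matrix(ws$relative[, -1])
  cc <- cov(R)
  expect_lt(max(abs(cc[upper.tri(cc)])) / max(diag(cc)), 1e-8)
  # nonzero-variance axis count is min(n - 1, 2k - 4)
  small <- relative_warps(random_landmarks(9, seed = 12)) |> suppressWarnings()
  expect_equal(sum(small$variance_fraction > 1e-12), 8)
})

test_that("alpha = 0 relative warps equal principal components of aligned coordinates", {
  lmk <- random_landmarks(35, sd = 0.004, seed = 13)
  ws <- relative_warps(lmk)
  arr <- ws$gpa$aligned
  n <- dim(arr)[3]
  flat <- t(apply(arr, 3, as.vector))
  # independent oracle: eigen-decomposition of the aligned-coordinate
  # covariance, scores by direct projection
  ctr <- scale(flat, scale = FALSE)
  eo <- eigen(cov(flat), symmetric = TRUE)
  oracle <- ctr %*% eo$vectors[, 1:10]
  for (j in 1:10) {
    r <- cor(oracle[, j], ws$relative[[paste0("rw", j)]])
    expect_gt(abs(r), 1 - 1e-6)
  }
})

test_that("relative warp scores are invariant to similarity transforms of the input", {
  lmk <- random_landmarks(25, seed = 14)
  base <- relative_warps(lmk)
  moved <- relative_warps(apply_similarity(lmk, seed = 15))
  keep <- which(base$variance_fraction > 1e-10)
  delta <- as.matrix(base$relative[keep + 1]) - as.matrix(moved$relative[keep + 1])
  expect_lt(max(abs(delta)), 1e-6)
})

test_that("axis sign convention makes repeated runs deterministic", {
  lmk <- random_landmarks(25, seed = 16)
  a <- relative_warps(lmk)
  b <- relative_warps(lmk)
  expect_identical(a$relative, b$relative)
  for (j in seq_len(a$n_axes)) {
    lj <- a$loadings_shape[, j]
    expect_gt(lj[which.max(abs(lj))], 0)
  }
})
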