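test_that("restricted likelihood matches the brute-force oracle on a 5-animal pedigree", {
  ped <- tibble::tibble(
    id = c("s", "d", "o1", "o2", "o3"),
    sire = c(NA, NA, "s", "s", "s"),
    dam = c(NA, NA, "d", "d", "d")
  )
  A <- additive_relationship(ped)
  set.seed(21)
  y <- rnorm(5)
  X <- matrix(1, 5, 1)
  for (theta in list(c(1, 1), c(0.3, 0.7), c(2.5, 0.1))) {
    oracle <- reml_oracle(theta, y, X, list(additive = A))
    fast <- morphherit:::reml_loglik_fn(y, X, list(additive = A))(theta)$loglik
    dense <- morphherit:::reml_loglik_dense(theta, y, X, list(additive = A))$loglik
    expect_equal(fast, oracle, tolerance = 1e-8)
    expect_equal(dense, oracle, tolerance = 1e-8)
  }
  # multi-component dense path against the oracle too
  Zd <- morphherit:::incidence(c("d", "d", "f1", "f1", "f2"))
  Rl <- list(additive = A, dam = tcrossprod(Zd))
  th <- c(0.4, 0.3, 0.6)
  expect_equal(
    morphherit:::reml_loglik_dense(th, y, X, Rl)$loglik,
    reml_oracle(th, y, X, Rl),
    tolerance = 1e-8
  )
})

test_that("pure-noise traits put the additive variance at the boundary", {
  ap <- assinica_pedigree(6)
  set.seed(4)
  d <- dplyr::filter(ap$ped, !is.na(family))
  d$y <- rnorm(nrow(d))
  fit <- animal_model(d, "y", ap$A)
  expect_lt(fit$h2, 0.15)
  red <- drop_random_term(fit, "additive")
  lrt <- lrt_varcomp(fit, red)
  expect_gte(lrt$statistic, 0)
  # with V_a at (or near) the boundary, full and reduced likelihoods coincide
  if (fit$h2 < 1e-6) expect_equal(fit$loglik, red$loglik, tolerance = 1e-6)
})

test_that("heritability is recovered for a strongly heritable trait with power", {
  ap <- assinica_pedigree(8)
  ps <- vapply(1:8, function(s) {
    d <- sim_trait(ap$ped, ap$A, V_a = 0.5, V_e = 0.5, seed = s)
    fit <- animal_model(d, "y", ap$A)
    lrt_varcomp(fit, drop_random_term(fit, "additive"))$p.value
  }, 0)
  expect_lt(median(ps), 0.05)
})

test_that("likelihood-ratio mechanics: identity, chi-square quantile, nesting checks", {
  ap <- assinica_pedigree(3)
  d <- sim_trait(ap$ped, ap$A, V_a = 0.3, V_e = 0.7, seed = 2)
  fit <- animal_model(d, "y", ap$A)
  expect_equal(lrt_varcomp(fit, fit)$statistic, 0)
  expect_equal(lrt_varcomp(fit, fit)$p.value, 1)
  expect_equal(morphherit:::lrt_pvalue(3.84), 0.05, tolerance = 0.001)
  expect_equal(
    morphherit:::lrt_pvalue(3.84, boundary = TRUE),
    0.025,
    tolerance = 0.001
  )
  other <- animal_model(d, "y", ap$A, random = c("additive", "dam"))
  expect_error(lrt_varcomp(fit, other), "drop exactly one")
})

test_that("estimates are invariant to translating or rescaling the response", {
  ap <- assinica_pedigree(5)
  d <- sim_trait(ap$ped, ap$A, V_a = 0.4, V_e = 0.6, seed = 9)
  f0 <- animal_model(d, "y", ap$A)
  f_shift <- animal_model(dplyr::mutate(d, y = y + 100), "y", ap$A)
  f_scale <- animal_model(dplyr::mutate(d, y = 10 * y), "y", ap$A)
  expect_equal(f_shift$h2, f0$h2, tolerance = 1e-6)
  expect_equal(f_scale$h2, f0$h2, tolerance = 1e-6)
  expect_equal(
    f_scale$components$variance,
    100 * f0$components$variance,
    tolerance = 1e-4
  )
})

test_that("with A = I the animal model matches the one-way ANOVA intraclass estimate", {
  # 40 unrelated 'families' of iid-deviating members: the additive variance
  # of an identity-relationship animal model plays the role of the
  # between-group variance when y is grouped; compare against the classic
  # ANOVA estimator sigma_b^2 = (MSB - MSW) / n0 on group-mean-structured data
  set.seed(31)
  n_g <- 40
  m <- 6
  grp <- factor(rep(seq_len(n_g), each = m))
  b <- rnorm(n_g, 0, sqrt(0.4))
  y <- b[as.integer(grp)] + rnorm(n_g * m, 0, sqrt(0.6))
  d <- tibble::tibble(id = paste0("i", seq_along(y)), g = grp, y = y)
  # group-structured covariance via a 'relationship' that is block identity:
  # equivalently fit the dam-style iid group term
  fit <- animal_model(d, "y", relationship = NULL, random = "dam", dam = "g")
  av <- anova(lm(y ~ grp))
  msb <- av$`Mean Sq`[1]
  msw <- av$`Mean Sq`[2]
  sigma_b2 <- (msb - msw) / m
  vb <- fit$components$variance[fit$components$term == "dam"]
  expect_equal(vb, sigma_b2, tolerance = 0.05 * sigma_b2 + 0.01)
  expect_equal(
    fit$components$variance[fit$components$term == "residual"],
    msw,
    tolerance = 0.05 * msw
  )
})

test_that("delta-method intervals have reasonable coverage at h2 = 0.5", {
  ap <- assinica_pedigree(8)
  hits <- vapply(1:12, function(s) {
    d <- sim_trait(ap$ped, ap$A, V_a = 0.5, V_e = 0.5, seed = 100 + s)
    fit <- animal_model(d, "y", ap$A)
    !is.na(fit$h2_se) && abs(fit$h2 - 0.5) <= 2 * fit$h2_se
  }, TRUE)
  expect_gte(mean(hits), 0.75)
})

test_that("singular fixed designs and confounded family terms are refused", {
  ap <- assinica_pedigree(3)
  d <- sim_trait(ap$ped, ap$A, V_a = 0.3, V_e = 0.7, seed = 6)
  d$dup <- 1 # aliased with the intercept
  expect_error(animal_model(d, "y", ap$A, fixed = ~dup), "aliased")
  # nested design: family == dam partition -> family term refused
  nd <- cross_design(12, 5, "nested")
  nped <- pedigree_from_design(nd, 4)
  nA <- additive_relationship(nped)
  doff <- dplyr::filter(nped, !is.na(family))
  doff$y <- rnorm(nrow(doff))
  expect_error(
    animal_model(doff, "y", nA, random = c("additive", "family")),
    class = "morphherit_confounded_family"
  )
  # split-egg-lot design: family strictly finer than dam -> family term allowed
  sd_ <- cross_design(20, 10, "split_egg_lot", n_split_dams = 8)
  sped <- pedigree_from_design(sd_, 3)
  sA <- additive_relationship(sped)
  soff <- dplyr::filter(sped, !is.na(family))
  set.seed(7)
  soff$y <- rnorm(nrow(soff))
  expect_s3_class(
    animal_model(soff, "y", sA, random = c("additive", "family")),
    "animal_model"
  )
})
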