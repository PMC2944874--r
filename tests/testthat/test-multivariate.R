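make_scores <- function(n_per = 20, p = 4, shift = NULL, seed = 1,
                        groups = c("a", "b", "c"), slope = NULL) {
  set.seed(seed)
  purrr::imap_dfr(setNames(seq_along(groups), groups), function(gi, g) {
    Y <- matrix(rnorm(n_per * p), n_per, p)
    if (!is.null(shift)) Y <- Y + matrix(shift[[gi]], n_per, p, byrow = TRUE)
    x <- runif(n_per, -1, 1)
    if (!is.null(slope)) Y <- Y + outer(x, slope[[gi]])
    out <- tibble::as_tibble(as.data.frame(Y))
    names(out) <- paste0("v", seq_len(p))
    dplyr::mutate(out, strain = g, log_csize = x, family = paste0(g, rep(1:4, length.out = n_per)))
  })
}

test_that("Wilks lambda is 1 for duplicated groups and reduces to ANOVA when p = 1", {
  set.seed(11)
  base <- tibble::tibble(v1 = rnorm(15), v2 = rnorm(15))
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, strain = "a"),
    dplyr::mutate(base, strain = "b")
  )
  w <- manova_wilks(dup, c("v1", "v2"))
  expect_equal(w$lambda, 1, tolerance = 1e-12)
  expect_equal(w$p.value, 1, tolerance = 1e-8)

  d <- make_scores(p = 1, seed = 12, shift = list(0, 0.8, -0.3))
  w1 <- manova_wilks(d, "v1")
  av <- anova(lm(v1 ~ strain, data = d))
  ssb <- av$`Sum Sq`[1]
  ssw <- av$`Sum Sq`[2]
  expect_equal(w1$lambda, ssw / (ssw + ssb), tolerance = 1e-10)
  expect_equal(w1$statistic, av$`F value`[1], tolerance = 1e-8)
  expect_equal(w1$p.value, av$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("Wilks lambda matches the W^-1 B eigenvalue identity and stats::manova", {
  d <- make_scores(seed = 13, shift = list(0, 0.5, -0.5))
  sc <- paste0("v", 1:4)
  w <- manova_wilks(d, sc)
  # independent eigen-oracle: Lambda = prod 1 / (1 + lambda_i), W^-1 B
  Y <- as.matrix(d[sc])
  g <- factor(d$strain)
  W <- matrix(0, 4, 4)
  for (lev in levels(g)) {
    Yg <- Y[g == lev, ]
    W <- W + crossprod(scale(Yg, scale = FALSE))
  }
  B <- crossprod(scale(Y, scale = FALSE)) - W
  lam <- Re(eigen(solve(W) %*% B)$values)
  expect_equal(w$lambda, prod(1 / (1 + lam)), tolerance = 1e-10)
  # library cross-check of the full F approximation
  sm <- summary(manova(Y ~ g), test = "Wilks")$stats
  expect_equal(w$lambda, sm[1, "Wilks"], tolerance = 1e-10)
  expect_equal(w$statistic, sm[1, "approx F"], tolerance = 1e-8)
  expect_equal(w$p.value, sm[1, "Pr(>F)"], tolerance = 1e-8)
})

test_that("MANCOVA interaction matches anova.mlm and flags degenerate inputs", {
  d <- make_scores(seed = 14, slope = list(c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0)))
  sc <- paste0("v", 1:4)
  out <- mancova_interaction(d, sc)
  Y <- as.matrix(d[sc])
  g <- factor(d$strain)
  x <- d$log_csize
  aw <- stats::anova(lm(Y ~ g + x + g:x), test = "Wilks")
  expect_equal(out$lambda, aw["g:x", "Wilks"], tolerance = 1e-8)
  expect_equal(out$p.value, aw["g:x", "Pr(>F)"], tolerance = 1e-6)
  expect_error(
    mancova_interaction(dplyr::filter(d, strain == "a"), sc),
    "single group"
  )
  expect_error(
    mancova_interaction(dplyr::mutate(d, log_csize = 1), sc),
    "constant"
  )
})

test_that("a tripled allometric slope in one group is detected", {
  hits <- vapply(1:10, function(s) {
    d <- make_scores(
      seed = 200 + s,
      slope = list(c(1, 0.5, 0, 0), c(1, 0.5, 0, 0), c(3, 1.5, 0, 0))
    )
    mancova_interaction(d, paste0("v", 1:4))$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("leave-one-out DFA separates distant groups and reports row percentages", {
  d <- make_scores(
    n_per = 30, seed = 15,
    shift = list(c(0, 0, 0, 0), c(10, 0, 0, 0), c(0, 10, 0, 0))
  )
  res <- dfa_loo(d, paste0("v", 1:4))
  pct <- as.matrix(res$confusion[, -1])
  expect_equal(unname(rowSums(pct)), rep(100, 3))
  expect_true(all(diag(pct) >= 95))
  # equal-priors LOO agrees with an MASS::lda cross-check on the same data
  ref <- MASS::lda(as.matrix(d[paste0("v", 1:4)]),
    grouping = factor(d$strain),
    prior = rep(1 / 3, 3), CV = TRUE
  )
  expect_equal(res$accuracy, 100 * mean(ref$class == d$strain))
})

test_that("family subsampling is seeded, bounded and reproducible", {
  d <- make_scores(n_per = 24, seed = 16, shift = list(0, 3, -3))
  r1 <- dfa_loo(d, paste0("v", 1:4), per_family_subsample = 4, seed = 99)
  r2 <- dfa_loo(d, paste0("v", 1:4), per_family_subsample = 4, seed = 99)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$n_used, 4 * 12)
  expect_error(
    dfa_loo(d, paste0("v", 1:4), per_family_subsample = 1000, seed = 1),
    "smallest family"
  )
  expect_error(dfa_loo(d, paste0("v", 1:4), per_family_subsample = 4), "seed")
})

test_that("repeated measures on family means finds a common time trend", {
  make_rm <- function(time_eff, strain_eff, seed) {
    set.seed(seed)
    tidyr::expand_grid(
      strain = c("a", "b", "c"), famno = 1:10, period = 1:3
    ) |>
      dplyr::mutate(
        family = paste0(strain, famno),
        rw1 = time_eff * period +
          strain_eff * (strain == "c") +
          rep(rnorm(30, 0, 0.5), each = 3) +
          rnorm(dplyr::n(), 0, 0.5)
      )
  }
  d <- make_rm(time_eff = 1, strain_eff = 0, seed = 17)
  res <- repeated_measures_family_means(d, "rw1")
  expect_equal(sort(unique(res$effect)), c("group", "group:period", "period"))
  expect_lt(res$p.value[res$effect == "period"], 1e-4)
  expect_gt(res$p.value[res$effect == "group:period"], 0.01)

  # interaction null calibration direction: no effects at all
  ps <- vapply(1:10, function(s) {
    r <- repeated_measures_family_means(make_rm(0, 0, 300 + s), "rw1")
    r$p.value[r$effect == "group:period"]
  }, 0)
  expect_gte(mean(ps > 0.05), 0.7)
})

test_that("degenerate repeated-measures designs are rejected or trimmed", {
  d <- tidyr::expand_grid(strain = "a", famno = 1, period = 1:3) |>
    dplyr::mutate(family = "f1", rw1 = rnorm(3))
  expect_error(
    repeated_measures_family_means(d, "rw1"),
    "between-family"
  )
  d2 <- tidyr::expand_grid(strain = c("a", "b"), famno = 1:4, period = 1:3) |>
    dplyr::mutate(family = paste0(strain, famno), rw1 = rnorm(24))
  d2 <- dplyr::filter(d2, !(family == "a1" & period > 1))
  expect_warning(repeated_measures_family_means(d2, "rw1"), "dropped")
})
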