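# Strain-level multivariate comparisons on warp scores: MANOVA (Wilks),
# homogeneity-of-slopes MANCOVA, leave-one-out discriminant reclassification,
# and split-plot repeated measures on family means.

# Wilks' lambda and Rao's F approximation. E = error scatter, H = hypothesis
# scatter, p = n variables, q = hypothesis df, v = error df.
wilks_rao <- function(E, H, p, q, v) {
  lambda <- det(E) / det(E + H)
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (v - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  Fstat <- if (lam_s > 0) (1 - lam_s) / lam_s * df2 / df1 else Inf
  tibble::tibble(
    lambda = lambda, statistic = Fstat,
    df1 = df1, df2 = df2,
    p.value = pf(Fstat, df1, df2, lower.tail = FALSE)
  )
}

# Reduce a score matrix to its leading principal components when the pooled
# within-group scatter would be singular; returns the (possibly truncated)
# matrix. `resid_rank` is the error degrees of freedom available.
guard_rank <- function(Y, resid_rank, context) {
  r <- qr(sweep(Y, 2, colMeans(Y)))$rank
  keep <- min(r, resid_rank - 1L, ncol(Y))
  if (keep < ncol(Y)) {
    rlang::inform(sprintf(
      "%s: score matrix truncated from %d to %d leading principal components to keep the within-group scatter nonsingular.",
      context, ncol(Y), keep
    ))
    pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
    Y <- pc$x[, seq_len(keep), drop = FALSE]
  }
  Y
}

#' MANOVA on warp scores (Wilks' lambda)
#'
#' One-way multivariate analysis of variance comparing groups (strains) on a
#' set of score columns, reported as Wilks' lambda `|W| / |W + B|` with
#' Rao's F approximation. If the pooled within-group scatter is singular the
#' scores are truncated to their leading principal components (with a
#' message).
#'
#' @param data One row per specimen.
#' @param scores Character vector of score column names (e.g. partial-warp
#'   columns).
#' @param group Grouping column name (default `"strain"`).
#' @return A tibble: `lambda`, `statistic` (Rao's F), `df1`, `df2`,
#'   `p.value`, `n`, `n_groups`, `n_vars`.
#' @export
manova_wilks <- function(data, scores, group = "strain") {
  stopifnot(all(c(scores, group) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop_morphherit("MANOVA needs >= 2 groups.")
  if (any(table(g) < 2)) stop_morphherit("every group needs >= 2 observations.")
  Y <- as.matrix(data[scores])
  n <- nrow(Y)
  Y <- guard_rank(Y, n - nlevels(g), "manova_wilks")
  p <- ncol(Y)
  grand <- colMeans(Y)
  Tot <- crossprod(sweep(Y, 2, grand))
  W <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yg <- Y[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Yg, 2, colMeans(Yg)))
  }
  B <- Tot - W
  out <- wilks_rao(W, B, p, q = nlevels(g) - 1L, v = n - nlevels(g))
  dplyr::mutate(out, n = n, n_groups = nlevels(g), n_vars = p)
}

#' Homogeneity-of-slopes MANCOVA on warp scores
#'
#' Tests whether the multivariate regression of scores on a covariate
#' (log10 centroid size) differs among groups — the group x covariate
#' interaction of the multivariate linear model, i.e. a test for
#' differences in allometric growth patterns among strains. Wilks' lambda
#' is formed from the residual scatter of the full (separate slopes) versus
#' common-slope models.
#'
#' @inheritParams manova_wilks
#' @param covariate Covariate column name (default `"log_csize"`).
#' @return A tibble as in [manova_wilks()].
#' @export
mancova_interaction <- function(data, scores, group = "strain",
                                covariate = "log_csize") {
  stopifnot(all(c(scores, group, covariate) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) {
    stop_morphherit("MANCOVA interaction is undefined for a single group.")
  }
  x <- as.numeric(data[[covariate]])
  spread <- tapply(x, g, function(v) diff(range(v)))
  if (any(spread <= 0)) {
    stop_morphherit("covariate is constant within at least one group.")
  }
  Y <- as.matrix(data[scores])
  n <- nrow(Y)
  ng <- nlevels(g)
  Y <- guard_rank(Y, n - 2L * ng, "mancova_interaction")
  p <- ncol(Y)
  full <- lm(Y ~ g * x)
  common <- lm(Y ~ g + x)
  E <- crossprod(stats::residuals(full))
  H <- crossprod(stats::residuals(common)) - E
  out <- wilks_rao(E, H, p, q = ng - 1L, v = n - 2L * ng)
  dplyr::mutate(out, n = n, n_groups = ng, n_vars = p)
}

#' Leave-one-out discriminant reclassification of groups
#'
#' Linear discriminant analysis with pooled covariance and equal priors
#' (group sizes here are breeding-design artifacts, not prevalences — note
#' this differs from proportional-prior defaults elsewhere), classifying
#' each observation with the rule refit without it (leave-one-out
#' cross-validation). Optionally an equal-count random subsample is drawn
#' from each family first, so family structure does not weight the rule.
#'
#' Classification is delegated to [MASS::lda()] with `CV = TRUE`.
#'
#' @inheritParams manova_wilks
#' @param family Family column name; required when subsampling.
#' @param per_family_subsample Number of fish sampled per family (must not
#'   exceed the smallest family); `NULL` uses all rows.
#' @param seed Seed for the subsample draw; required when subsampling.
#' @return A `dfa_loo` object: `confusion` (tibble of row percentages,
#'   original group x classified group), `accuracy` (overall % correct),
#'   `n_used`.
#' @export
dfa_loo <- function(data, scores, group = "strain", family = "family",
                    per_family_subsample = NULL, seed = NULL) {
  stopifnot(all(c(scores, group) %in% names(data)))
  data <- as.data.frame(data)
  if (!is.null(per_family_subsample)) {
    if (is.null(seed)) stop_morphherit("`seed` is required when subsampling by family.")
    stopifnot(family %in% names(data))
    m <- check_count(per_family_subsample, "per_family_subsample")
    sizes <- table(data[[family]])
    if (m > min(sizes)) {
      stop_morphherit(sprintf(
        "per_family_subsample (%d) exceeds the smallest family size (%d).",
        m, min(sizes)
      ))
    }
    rows <- with_seed(seed, unlist(lapply(
      split(seq_len(nrow(data)), data[[family]]),
      function(ix) sample(ix, m)
    ), use.names = FALSE))
    data <- data[sort(rows), , drop = FALSE]
  }
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop_morphherit("DFA needs >= 2 groups.")
  Y <- as.matrix(data[scores])
  Y <- guard_rank(Y, nrow(Y) - nlevels(g), "dfa_loo")
  prior <- rep(1 / nlevels(g), nlevels(g))
  cv <- MASS::lda(Y, grouping = g, prior = prior, CV = TRUE)
  tab <- table(original = g, classified = cv$class)
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  confusion <- tibble::as_tibble(as.data.frame.matrix(pct), rownames = "original")
  structure(
    list(
      confusion = confusion,
      accuracy = 100 * mean(as.character(g) == as.character(cv$class)),
      n_used = nrow(Y),
      seed = seed
    ),
    class = "dfa_loo"
  )
}

#' @method print dfa_loo
#' @export
print.dfa_loo <- function(x, ...) {
  cat(sprintf(
    "<dfa_loo: %d observations, overall accuracy %.2f%%>\n",
    x$n_used, x$accuracy
  ))
  print(x$confusion)
  invisible(x)
}

#' @rdname dfa_loo
#' @param x A `dfa_loo` object.
#' @param ... Unused.
#' @method tidy dfa_loo
#' @export
tidy.dfa_loo <- function(x, ...) {
  tidyr::pivot_longer(x$confusion, -"original",
    names_to = "classified", values_to = "percent"
  )
}

#' Repeated measures on family-mean warp scores
#'
#' Tests whether strain differences in morphology change over sampling
#' periods: family-mean scores are the dependent variables, analysed per
#' warp by a split-plot ANOVA with strain as the between-family factor and
#' period as the within-family (repeated) factor. No sphericity correction
#' is applied. Families observed in fewer than two periods are dropped with
#' a warning.
#'
#' @param data One row per family x period, or per fish (rows are averaged
#'   within family x period first).
#' @param scores Score column names (e.g. the first six relative warps).
#' @param group,family,period Column names.
#' @return A tibble with one row per warp x effect: `score`, `effect`
#'   (`group`, `period`, `group:period`), `df`, `df_error`, `statistic`,
#'   `p.value`.
#' @export
repeated_measures_family_means <- function(data, scores,
                                           group = "strain", family = "family",
                                           period = "period") {
  stopifnot(all(c(scores, group, family, period) %in% names(data)))
  fm <- data |>
    dplyr::group_by(
      g = factor(.data[[group]]), fam = factor(.data[[family]]),
      per = factor(.data[[period]])
    ) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(scores), mean), .groups = "drop")
  nper <- fm |>
    dplyr::count(.data$fam) |>
    dplyr::filter(.data$n < 2)
  if (nrow(nper) > 0) {
    rlang::warn(sprintf(
      "family(ies) observed in < 2 periods dropped: %s",
      paste(nper$fam, collapse = ", ")
    ))
    fm <- dplyr::filter(fm, !.data$fam %in% nper$fam)
  }
  fm <- dplyr::mutate(fm, fam = droplevels(.data$fam), g = droplevels(.data$g))
  if (nlevels(fm$fam) - nlevels(fm$g) < 1) {
    stop_morphherit("no between-family degrees of freedom (too few families).")
  }
  purrr::map_dfr(scores, function(sc) {
    df <- data.frame(y = fm[[sc]], g = fm$g, per = fm$per, fam = fm$fam)
    fit <- aov(y ~ g * per + Error(fam), data = df)
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      tab <- stratum[[1]]
      terms <- trimws(rownames(tab))
      res <- which(terms == "Residuals")
      for (i in seq_len(nrow(tab))) {
        if (i == res) next
        effect <- switch(terms[i],
          g = "group", per = "period", `g:per` = "group:period", terms[i]
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          score = sc, effect = effect,
          df = tab$Df[i], df_error = tab$Df[res],
          statistic = tab$`F value`[i], p.value = tab$`Pr(>F)`[i]
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
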