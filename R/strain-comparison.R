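#' Mixed-model strain comparison with Tukey post-hoc contrasts
#'
#' Fits a linear mixed model with strain (and optionally maturation status)
#' as fixed effects and sire and dam as crossed random intercepts, then
#' compares strains on least-squares (estimated marginal) means with
#' Tukey-adjusted pairwise p-values. This is the per-trait, per-period
#' strain screen conventionally applied to relative warp scores, length,
#' weight, condition factor and development rate.
#'
#' Model fitting is delegated to [lme4::lmer()]; marginal means and the
#' Tukey-Kramer adjustment to [emmeans::emmeans()].
#'
#' @param data One row per fish: the trait column, `strain`, `sire`, `dam`
#'   and any extra fixed-effect columns.
#' @param trait Trait column name.
#' @param fixed Extra fixed-effect column names beyond strain (e.g.
#'   `"mature"`); omitted automatically if constant in `data`.
#' @param strain,sire,dam Column names.
#' @param df Degrees-of-freedom method passed to emmeans (default
#'   Satterthwaite).
#' @return A `strain_comparison` object with `emmeans` (tibble of LS-means
#'   per strain), `contrasts` (tibble of Tukey-adjusted pairwise
#'   comparisons), `varcomp` (sire/dam/residual variances), and the lmer
#'   `fit`.
#' @export
strain_comparison <- function(data, trait, fixed = character(),
                              strain = "strain", sire = "sire", dam = "dam",
                              df = "satterthwaite") {
  stopifnot(all(c(trait, strain, sire, dam) %in% names(data)))
  data <- as.data.frame(data)
  data[[strain]] <- factor(data[[strain]])
  if (nlevels(data[[strain]]) < 2) {
    stop_morphherit("strain comparison needs >= 2 strains.")
  }
  fam_per_strain <- tapply(
    interaction(data[[sire]], data[[dam]], drop = TRUE),
    data[[strain]], function(f) length(unique(f))
  )
  if (any(fam_per_strain < 2)) {
    rlang::warn(sprintf(
      "strain(s) with a single family: %s; comparison retained.",
      paste(names(fam_per_strain)[fam_per_strain < 2], collapse = ", ")
    ))
  }
  fixed <- fixed[vapply(fixed, function(v) length(unique(data[[v]])) > 1, logical(1))]
  rhs <- paste(c(strain, fixed, sprintf("(1 | %s) + (1 | %s)", sire, dam)),
    collapse = " + "
  )
  form <- stats::as.formula(paste(trait, "~", rhs))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  emm <- emmeans::emmeans(fit, specs = strain, lmer.df = df)
  cmp <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      trait = trait,
      emmeans = tibble::as_tibble(as.data.frame(emm)),
      contrasts = tibble::as_tibble(as.data.frame(cmp)),
      varcomp = tibble::tibble(term = vc$grp, variance = vc$vcov),
      fit = fit
    ),
    class = "strain_comparison"
  )
}

#' @method print strain_comparison
#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("<strain_comparison: %s>\n", x$trait))
  print(x$contrasts)
  invisible(x)
}

#' @rdname strain_comparison
#' @param x A `strain_comparison` object.
#' @param ... Unused.
#' @method tidy strain_comparison
#' @export
tidy.strain_comparison <- function(x, ...) {
  x$contrasts
}

#' @rdname strain_comparison
#' @method glance strain_comparison
#' @export
glance.strain_comparison <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    n = stats::nobs(x$fit),
    min_p = min(x$contrasts$p.value),
    n_significant = sum(x$contrasts$p.value < 0.05)
  )
}
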