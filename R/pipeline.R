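# End-to-end orchestration: landmarks -> warps -> condition -> heritability
# -> multivariate strain statistics, with deterministic seeding and report
# tables.

#' Run the full shape-heritability analysis pipeline
#'
#' Executes the complete analysis chain on either a simulated study or
#' files on disk: per-period relative warps (one shape space per period,
#' all strains pooled), relative condition factor, per-strain and
#' pooled-strain animal-model heritability for the leading warps, length
#' and weight (with likelihood-ratio tests of the additive component),
#' MANOVA and allometry MANCOVA on partial warps, leave-one-out
#' discriminant reclassification, and repeated measures on family means in
#' a common (all-period) warp space.
#'
#' @param config A named list (or path to a YAML file). Recognised fields:
#'   * `simulate`: list of [sim_params()] overrides -> data are simulated,
#'   * `inputs`: list with `tps` (character vector of per-period TPS
#'     paths), `pedigree` (CSV path) and `phenotypes` (CSV path),
#'   * `n_warps`: number of leading relative warps analysed (default 6),
#'   * `random`: random terms for the heritability models (default
#'     `"additive"`),
#'   * `per_family_subsample`: DFA subsample size (default the smallest
#'     family's sampled count),
#'   * `seed`: master seed (default 1),
#'   * `out_dir`: optional directory; report tables are written as headered
#'     CSV plus a plain-text summary and run log.
#' @return A `pipeline_report` list of tibbles: `variance_fractions`,
#'   `heritability`, `wilks`, `dfa` (list of confusion tibbles per period),
#'   `repeated_measures`, `strain_comparisons`, `condition`, plus `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_morphherit("reading YAML configs requires the yaml package.")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    stop_morphherit("config must contain either `simulate` or `inputs`, not both.")
  }
  seed <- config$seed %||% 1L
  n_warps <- config$n_warps %||% 6L
  random <- config$random %||% "additive"
  log_lines <- c(
    sprintf("morphherit %s", as.character(utils::packageVersion("morphherit"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("config hash: %s", rlang::hash(config))
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_morphherit(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- stage: data -----------------------------------------------------------
  dat <- stage("load", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      lmk <- purrr::imap_dfr(inp$tps, function(p, i) {
        dplyr::mutate(read_tps(p), period = as.integer(i), .before = 1)
      })
      list(
        landmarks = lmk,
        pedigree = read_pedigree(inp$pedigree),
        phenotypes = tibble::as_tibble(utils::read.csv(inp$phenotypes))
      )
    } else {
      sim <- do.call(sim_params, config$simulate %||% list())
      st <- simulate_study(sim, seed = seed)
      st[c("landmarks", "pedigree", "phenotypes")]
    }
  })
  ped <- dat$pedigree
  phen <- dat$phenotypes
  A <- stage("relationship", additive_relationship(ped))
  periods <- sort(unique(dat$landmarks$period))
  n_warps <- min(n_warps, 2L * sum(dat$landmarks$id == dat$landmarks$id[1]) - 4L)
  log_lines <- c(log_lines, sprintf(
    "periods: %s; warps analysed: %d",
    paste(periods, collapse = ","), n_warps
  ))

  # --- stage: morphometrics per period --------------------------------------
  morpho <- stage("morphometrics", lapply(periods, function(p) {
    lp <- dplyr::filter(dat$landmarks, .data$period == p)
    ws <- relative_warps(dplyr::select(lp, -"period"))
    scores <- dplyr::left_join(ws$relative,
      dplyr::left_join(ws$partial, ws$gpa$centroid_sizes, by = "id"),
      by = "id"
    )
    list(ws = ws, scores = dplyr::mutate(scores, log_csize = log10(.data$csize)))
  }))
  names(morpho) <- paste0("period", periods)
  varfrac <- purrr::imap_dfr(morpho, function(m, nm) {
    tibble::tibble(
      period = as.integer(sub("period", "", nm)),
      warp = seq_along(m$ws$variance_fraction),
      variance_fraction = m$ws$variance_fraction
    )
  })

  # --- stage: condition ------------------------------------------------------
  wl <- stage("condition", fit_weight_length(phen))
  phen <- relative_condition(phen, wl)
  condition <- tibble::tibble(a = wl$a, b = wl$b, n = wl$n, mean_kn = mean(phen$kn))

  # join warp scores onto phenotypes per period
  id_col <- if ("fish_id" %in% names(phen)) "fish_id" else "id"
  full <- purrr::map_dfr(periods, function(p) {
    dplyr::inner_join(
      dplyr::filter(phen, .data$period == p),
      morpho[[paste0("period", p)]]$scores,
      by = "id"
    )
  })

  # --- stage: heritability ---------------------------------------------------
  traits <- c(paste0("rw", seq_len(n_warps)), "length", "weight")
  herit <- stage("heritability", purrr::map_dfr(periods, function(p) {
    dp <- dplyr::filter(full, .data$period == p)
    fixed_cols <- if (p > 1 && length(unique(dp$mature)) > 1) "mature" else character()
    groups <- c(as.list(unique(dp$strain)), list(NULL))
    purrr::map_dfr(groups, function(strn) {
      d <- if (is.null(strn)) dp else dplyr::filter(dp, .data$strain == strn)
      fixed <- make_fixed_formula(c(fixed_cols, if (is.null(strn)) "strain"))
      purrr::map_dfr(traits, function(tr) {
        fit <- animal_model(d, tr,
          relationship = A, fixed = fixed,
          random = random, id = id_col
        )
        lrt <- lrt_varcomp(fit, drop_random_term(fit, "additive"))
        tibble::tibble(
          period = p, strain = strn %||% "pooled", trait = tr, n = fit$n,
          V_a = fit$components$variance[fit$components$term == "additive"],
          V_e = fit$components$variance[fit$components$term == "residual"],
          V_m = fit$m2 * fit$V_p, V_p = fit$V_p,
          h2 = fit$h2, h2_se = fit$h2_se,
          m2 = fit$m2, m2_se = fit$m2_se,
          lrt_statistic = lrt$statistic, lrt_p = lrt$p.value
        )
      })
    })
  }))

  # --- stage: multivariate strain statistics --------------------------------
  pw_cols <- grep("^(pw|uni)", names(full), value = TRUE)
  wilks <- stage("manova", purrr::map_dfr(periods, function(p) {
    dp <- dplyr::filter(full, .data$period == p)
    dplyr::bind_rows(
      dplyr::mutate(manova_wilks(dp, pw_cols), test = "manova", period = p),
      dplyr::mutate(mancova_interaction(dp, pw_cols), test = "mancova_interaction", period = p)
    )
  }))
  dfa_seeds <- split_seed(seed, length(periods))
  dfa <- stage("dfa", lapply(seq_along(periods), function(i) {
    dp <- dplyr::filter(full, .data$period == periods[i])
    m <- config$per_family_subsample %||% min(table(dp$family))
    dfa_loo(dp, pw_cols,
      per_family_subsample = m, seed = dfa_seeds[i]
    )$confusion
  }))
  names(dfa) <- paste0("period", periods)

  # repeated measures in one common shape space spanning all periods
  rm_tab <- if (length(periods) < 2) {
    tibble::tibble(
      score = character(), effect = character(), df = numeric(),
      df_error = numeric(), statistic = numeric(), p.value = numeric()
    )
  } else {
    stage("repeated_measures", {
    ws_all <- relative_warps(dplyr::select(dat$landmarks, -"period"))
    common <- dplyr::inner_join(
      phen, ws_all$relative,
      by = "id"
    )
      repeated_measures_family_means(
        common, paste0("rw", seq_len(n_warps))
      )
    })
  }

  strain_cmp <- stage("strain_comparison", purrr::map_dfr(periods, function(p) {
    dp <- dplyr::filter(full, .data$period == p)
    purrr::map_dfr(c(paste0("rw", seq_len(n_warps)), "length", "weight", "kn"), function(tr) {
      sc <- strain_comparison(dp, tr, fixed = if (p > 1) "mature" else character())
      dplyr::mutate(tidy(sc), trait = tr, period = p, .before = 1)
    })
  }))

  report <- structure(
    list(
      variance_fractions = varfrac,
      heritability = herit,
      wilks = wilks,
      dfa = dfa,
      repeated_measures = rm_tab,
      strain_comparisons = strain_cmp,
      condition = condition,
      log = log_lines
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

make_fixed_formula <- function(cols) {
  if (!length(cols)) {
    return(~1)
  }
  stats::as.formula(paste("~", paste(cols, collapse = " + ")))
}

#' @method print pipeline_report
#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf(
    "  heritability: %d fits; wilks: %d tests; dfa: %d period(s)\n",
    nrow(x$heritability), nrow(x$wilks), length(x$dfa)
  ))
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tabs <- c(
    "variance_fractions", "heritability", "wilks",
    "repeated_measures", "strain_comparisons", "condition"
  )
  for (nm in tabs) {
    utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
      row.names = FALSE
    )
  }
  for (nm in names(report$dfa)) {
    utils::write.csv(report$dfa[[nm]],
      file.path(out_dir, paste0("dfa_confusion_", nm, ".csv")),
      row.names = FALSE
    )
  }
  summary_lines <- c(
    report$log,
    "",
    sprintf(
      "significant heritabilities (LRT p < 0.05): %d / %d",
      sum(report$heritability$lrt_p < 0.05), nrow(report$heritability)
    ),
    sprintf(
      "median h2: %.2f",
      median(report$heritability$h2, na.rm = TRUE)
    )
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
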