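# Synthetic common-garden study generator: breeding designs, latent shape
# and size traits with known variance components, landmark configurations
# under nuisance digitization transforms, and size/condition phenotypes.

#' The three default hatchery-strain breeding designs
#'
#' Strain A: 12 dams x 5 sires, full-sib families nested within sires (each
#' sire 2-3 dams) -> 12 families. Strain B: 15 dams x 10 sires partial
#' factorial (sire x 3 dams, dam x 2 sires) -> 30 families. Strain C: 20
#' dams x 10 sires with the egg lots of 8 dams split between 2 sires -> 28
#' families. 70 half-sib families in total.
#'
#' @return Named list of [cross_design()] objects.
#' @export
default_designs <- function() {
  list(
    siskiwit = cross_design(12, 5, "nested"),
    assinica = cross_design(15, 10, "partial_factorial",
      dams_per_sire = 3, sires_per_dam = 2
    ),
    iron_river = cross_design(20, 10, "split_egg_lot", n_split_dams = 8)
  )
}

#' Template 13-landmark salmonid body shape
#'
#' A hand-coded 13-landmark outline of a salmonid in the conventional
#' ordering (snout tip, posterior neurocranium, dorsal fin origin and
#' insertion, adipose fin, dorsal and ventral caudal membrane attachments,
#' middle caudal rays, anal fin insertion and origin, pelvic fin, pectoral
#' fin, posterior maxillary), centered and scaled to unit centroid size.
#'
#' @return A 13 x 2 matrix.
#' @export
default_mean_shape <- function() {
  X <- matrix(c(
    0.00, 0.000, # 1 anterior tip of snout
    0.18, 0.100, # 2 posterior neurocranium
    0.42, 0.140, # 3 dorsal fin origin
    0.55, 0.130, # 4 dorsal fin insertion
    0.74, 0.100, # 5 adipose fin origin
    0.88, 0.070, # 6 dorsal caudal membrane attachment
    0.95, 0.000, # 7 base of middle caudal rays
    0.88, -0.060, # 8 ventral caudal membrane attachment
    0.76, -0.080, # 9 anal fin insertion
    0.68, -0.100, # 10 anal fin origin
    0.48, -0.120, # 11 pelvic fin origin
    0.22, -0.090, # 12 pectoral fin origin
    0.12, -0.020 # 13 posterior end of maxillary
  ), ncol = 2, byrow = TRUE)
  X <- sweep(X, 2, colMeans(X))
  X / sqrt(sum(X^2))
}

# Orthonormal, centered, non-affine shape directions: y-deformations along
# the two smallest-bending-energy principal warps of the template (large
# scale body-depth / caudal-peduncle-like deformations).
default_effect_basis <- function(mean_shape, q = 2) {
  wb <- warp_basis(mean_shape)
  pw <- wb$principal_warps
  m <- ncol(pw)
  out <- vector("list", q)
  for (t in seq_len(q)) {
    e <- pw[, m - t + 1L]
    out[[t]] <- cbind(0, e) # pure dorso-ventral deformation
  }
  out
}

#' Simulation parameters for a synthetic common-garden study
#'
#' Defaults emulate a three-strain hatchery experiment: the three printed
#' breeding designs (70 families), three sampling periods with declining
#' per-family sample sizes, two latent heritable shape traits expressed
#' along fixed orthonormal non-affine deformation directions, allometric
#' length-weight growth, nuisance digitization transforms, and iid landmark
#' noise. Variance components are on the latent-trait scale and define the
#' true heritability exactly as `V_a / (V_a + V_m + V_c + V_e)`.
#'
#' @param ... Overrides of any default parameter (see the returned list).
#' @return A `sim_params` list.
#' @export
sim_params <- function(...) {
  mean_shape <- default_mean_shape()
  p <- list(
    designs = default_designs(),
    n_per_family = c(10L, 8L, 5L), # sampled fish per family per period
    periods = 3L,
    # latent shape traits (unit phenotypic scale): V_a, V_m, V_c, V_e
    shape_vc = list(
      c(V_a = 0.5, V_m = 0.05, V_c = 0.05, V_e = 0.4),
      c(V_a = 0.3, V_m = 0.05, V_c = 0.05, V_e = 0.6)
    ),
    effect_scale = 0.02, # Procrustes units per latent sd
    mean_shape = mean_shape,
    effect_basis = NULL, # default: low-bending-energy y-deformations
    strain_shape_shift = c(siskiwit = -0.5, assinica = 0.5, iron_river = 0), # latent units, trait 1
    period_drift = c(0, 0.3, 0.6), # latent units, trait 2
    # length (mm): variance components and means
    length_vc = c(V_a = 25, V_m = 2.5, V_c = 2.5, V_e = 20),
    length_period_mean = c(60, 95, 125),
    strain_length_shift = c(siskiwit = 0, assinica = 5, iron_river = -5),
    maturation_rate = 0.2, # periods 2-3
    maturation_length_effect = -4,
    # allometric weight-length: log10 W = a + b log10 L + deviations
    allometry = c(a = -5, b = 3),
    weight_logdev_vc = c(V_a = 2e-4, V_m = 2e-5, V_c = 2e-5, V_e = 1.6e-4),
    # nuisance digitization transforms and landmark noise
    rotation_range = c(-pi, pi),
    translation_range = c(-1, 1),
    scale_range = c(0.5, 2),
    landmark_noise_sd = 0.002,
    # dam-level traits
    egg_diameter_mean = 4.5, egg_diameter_sd = 0.15,
    atu_mean = 475, atu_sd = 20,
    seed = 20061109
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_morphherit(sprintf(
      "unknown simulation parameter(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  p[names(dots)] <- dots # wholesale replacement, no recursive merging
  if (is.null(p$effect_basis)) {
    p$effect_basis <- default_effect_basis(p$mean_shape, length(p$shape_vc))
  }
  check_effect_basis(p$effect_basis, nrow(p$mean_shape))
  for (vc in c(p$shape_vc, list(p$length_vc, p$weight_logdev_vc))) {
    if (any(vc < 0)) stop_morphherit("variance components must be non-negative.")
  }
  structure(p, class = "sim_params")
}

check_effect_basis <- function(basis, k) {
  vecs <- sapply(basis, as.vector)
  if (nrow(vecs) != 2 * k) stop_morphherit("effect basis dimension mismatch.")
  gram <- crossprod(vecs)
  if (max(abs(gram - diag(ncol(vecs)))) > 1e-8) {
    stop_morphherit("effect basis must be orthonormal.")
  }
  ctr <- sapply(basis, function(B) max(abs(colMeans(B))))
  if (max(ctr) > 1e-8) stop_morphherit("effect basis must be centered.")
  invisible(TRUE)
}

#' Draw breeding values with pedigree covariance
#'
#' One draw from a zero-mean multivariate normal with covariance `A * V_a`,
#' via the eigendecomposition square root of the (positive semidefinite)
#' relationship matrix. Deterministic per seed.
#'
#' @param A Additive relationship matrix.
#' @param V_a Additive genetic variance (>= 0).
#' @param seed Integer seed.
#' @return Named vector of breeding values in `rownames(A)` order.
#' @export
simulate_breeding_values <- function(A, V_a, seed) {
  if (!is.numeric(V_a) || V_a < 0) stop_morphherit("`V_a` must be non-negative.")
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    stop_morphherit("relationship matrix is not positive semidefinite.")
  }
  Rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  z <- with_seed(seed, rnorm(nrow(A)))
  setNames(drop(Rt %*% z) * sqrt(V_a), rownames(A))
}

# Draw one latent trait for every pedigree member: additive + dam + family
# + individual environment, with the stated variance components.
sim_latent_trait <- function(ped, A, vc, seeds) {
  bv <- simulate_breeding_values(A, vc[["V_a"]], seeds[1])
  dams <- unique(na.omit(ped$dam))
  fams <- unique(na.omit(ped$family))
  de <- with_seed(seeds[2], setNames(rnorm(length(dams), 0, sqrt(vc[["V_m"]])), dams))
  fe <- with_seed(seeds[3], setNames(rnorm(length(fams), 0, sqrt(vc[["V_c"]])), fams))
  ee <- with_seed(seeds[4], setNames(rnorm(nrow(ped), 0, sqrt(vc[["V_e"]])), ped$id))
  val <- bv[ped$id] + ee[ped$id]
  has_dam <- !is.na(ped$dam)
  val[has_dam] <- val[has_dam] + de[ped$dam[has_dam]]
  has_fam <- !is.na(ped$family)
  val[has_fam] <- val[has_fam] + fe[ped$family[has_fam]]
  list(value = setNames(val, ped$id), bv = bv)
}

#' Simulate a complete common-garden study
#'
#' Generates the full synthetic dataset: a multi-strain pedigree from the
#' breeding designs, latent shape and size traits with the stated additive
#' / dam / family / residual variance structure, landmark configurations
#' per sampling period (template deformed along the effect basis, then
#' passed through a random similarity transform with iid landmark noise),
#' and a phenotype table (length, weight, maturation) plus dam-level egg
#' diameter and development-rate (ATU) traits.
#'
#' @param params A [sim_params()] list.
#' @param seed Master seed (overrides `params$seed` when given); all
#'   sub-generators draw from seeds split off this one, so adding a stage
#'   never perturbs earlier draws.
#' @return A `sim_study` list: `pedigree`, `relationship` (A over the whole
#'   pedigree), `phenotypes` (tibble, one row per sampled fish x period),
#'   `landmarks` (long tibble with `period` column), `dam_traits`, and
#'   `truth` (all parameters plus per-trait expected heritabilities and the
#'   drawn breeding values).
#' @export
simulate_study <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- seed %||% params$seed
  seeds <- split_seed(seed, 64)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  ped <- purrr::imap_dfr(
    params$designs,
    function(d, nm) {
      pedigree_from_design(d, max(params$n_per_family), strain = nm)
    }
  )
  A <- additive_relationship(ped)

  q <- length(params$shape_vc)
  shape_traits <- lapply(seq_len(q), function(t) {
    sim_latent_trait(ped, A, params$shape_vc[[t]], vapply(1:4, function(i) next_seed(), 0))
  })
  len_trait <- sim_latent_trait(ped, A, params$length_vc, vapply(1:4, function(i) next_seed(), 0))
  wdev_trait <- sim_latent_trait(ped, A, params$weight_logdev_vc, vapply(1:4, function(i) next_seed(), 0))

  off <- dplyr::filter(ped, !is.na(.data$family))
  # which fish are sampled at each period (seeded, per family)
  sample_rows <- lapply(seq_len(params$periods), function(p) {
    m <- params$n_per_family[p]
    s <- next_seed()
    with_seed(s, unlist(lapply(
      split(seq_len(nrow(off)), off$family),
      function(ix) sample(ix, min(m, length(ix)))
    ), use.names = FALSE))
  })

  k <- nrow(params$mean_shape)
  phen <- list()
  lmk <- list()
  mat_seeds <- vapply(seq_len(params$periods), function(i) next_seed(), 0)
  nuis_seeds <- vapply(seq_len(params$periods), function(i) next_seed(), 0)
  noise_seeds <- vapply(seq_len(params$periods), function(i) next_seed(), 0)
  for (p in seq_len(params$periods)) {
    rows <- sort(sample_rows[[p]])
    fish <- off[rows, ]
    n <- nrow(fish)
    shift1 <- unname(params$strain_shape_shift[fish$strain])
    lat <- sapply(seq_len(q), function(t) {
      v <- shape_traits[[t]]$value[fish$id]
      if (t == 1) v <- v + shift1
      if (t == 2) v <- v + params$period_drift[p]
      v
    })
    configs <- array(0, dim = c(k, 2, n), dimnames = list(NULL, c("x", "y"), paste0(fish$id, "_p", p)))
    for (i in seq_len(n)) {
      X <- params$mean_shape
      for (t in seq_len(q)) {
        X <- X + params$effect_scale * lat[i, t] * params$effect_basis[[t]]
      }
      configs[, , i] <- X
    }
    # nuisance similarity transforms + landmark noise
    nuis <- with_seed(nuis_seeds[p], list(
      ang = runif(n, params$rotation_range[1], params$rotation_range[2]),
      tx = runif(n, params$translation_range[1], params$translation_range[2]),
      ty = runif(n, params$translation_range[1], params$translation_range[2]),
      sc = runif(n, params$scale_range[1], params$scale_range[2])
    ))
    noise <- with_seed(noise_seeds[p], array(
      rnorm(k * 2 * n, 0, params$landmark_noise_sd),
      dim = c(k, 2, n)
    ))
    for (i in seq_len(n)) {
      X <- configs[, , i] + noise[, , i]
      R <- matrix(c(cos(nuis$ang[i]), sin(nuis$ang[i]), -sin(nuis$ang[i]), cos(nuis$ang[i])), 2)
      X <- nuis$sc[i] * X %*% t(R)
      X[, 1] <- X[, 1] + nuis$tx[i]
      X[, 2] <- X[, 2] + nuis$ty[i]
      configs[, , i] <- X
    }
    lmk[[p]] <- dplyr::mutate(array_to_landmarks(configs), period = p, .before = 1)

    mature <- if (p == 1) {
      rep(FALSE, n)
    } else {
      with_seed(mat_seeds[p], runif(n) < params$maturation_rate)
    }
    len <- params$length_period_mean[p] +
      unname(params$strain_length_shift[fish$strain]) +
      len_trait$value[fish$id] +
      ifelse(mature, params$maturation_length_effect, 0)
    len <- pmax(len, 1)
    w <- 10^(params$allometry[["a"]] + params$allometry[["b"]] * log10(len) +
      wdev_trait$value[fish$id])
    phen[[p]] <- tibble::tibble(
      id = paste0(fish$id, "_p", p),
      fish_id = fish$id,
      family = fish$family, strain = fish$strain,
      sire = fish$sire, dam = fish$dam,
      period = p, length = len, weight = unname(w), mature = mature
    )
  }

  dam_rows <- dplyr::filter(ped, is.na(.data$sire) & grepl("_D", .data$id))
  dam_traits <- with_seed(next_seed(), tibble::tibble(
    dam = dam_rows$id, strain = dam_rows$strain,
    egg_diameter = rnorm(nrow(dam_rows), params$egg_diameter_mean, params$egg_diameter_sd),
    atu = rnorm(nrow(dam_rows), params$atu_mean, params$atu_sd)
  ))

  truth <- list(
    params = params, seed = seed,
    expected_h2_shape = vapply(params$shape_vc, function(vc) vc[["V_a"]] / sum(vc), 0),
    expected_h2_length = params$length_vc[["V_a"]] / sum(params$length_vc),
    breeding_values = c(
      setNames(
        lapply(shape_traits, function(t) t$bv),
        paste0("shape", seq_len(q))
      ),
      list(length = len_trait$bv)
    )
  )
  structure(
    list(
      pedigree = ped, relationship = A,
      phenotypes = dplyr::bind_rows(phen),
      landmarks = dplyr::bind_rows(lmk),
      dam_traits = dam_traits,
      truth = truth
    ),
    class = "sim_study"
  )
}

#' @method print sim_study
#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study: %d pedigree members, %d families, %d measurements over %d period(s)>\n",
    nrow(x$pedigree), length(unique(na.omit(x$pedigree$family))),
    nrow(x$phenotypes), max(x$phenotypes$period)
  ))
  invisible(x)
}

#' Simulate only the landmark part of a study
#'
#' @inheritParams simulate_study
#' @return Long landmark tibble (with `period`), plus the truth record as
#'   attribute `"truth"`.
#' @export
simulate_shapes <- function(params = sim_params(), seed = NULL) {
  st <- simulate_study(params, seed)
  out <- st$landmarks
  attr(out, "truth") <- st$truth
  out
}

#' Simulate only the size/condition phenotype part of a study
#'
#' @inheritParams simulate_study
#' @return Phenotype tibble with the truth record as attribute `"truth"`.
#' @export
simulate_size <- function(params = sim_params(), seed = NULL) {
  st <- simulate_study(params, seed)
  out <- st$phenotypes
  attr(out, "truth") <- st$truth
  out
}

#' Write a simulated study to a fixture file tree
#'
#' Emits `landmarks_period<p>.tps` per period, `pedigree.csv`,
#' `phenotypes.csv`, `dam_traits.csv` and `truth.json`. Byte-identical
#' across runs with the same seed.
#'
#' @inheritParams simulate_study
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `sim_study` object.
#' @export
write_fixture_study <- function(params = sim_params(), out_dir, seed = NULL) {
  st <- simulate_study(params, seed)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_morphherit(sprintf("cannot create output directory '%s'.", out_dir))
  }
  for (p in sort(unique(st$landmarks$period))) {
    write_tps(
      dplyr::filter(st$landmarks, .data$period == p),
      file.path(out_dir, sprintf("landmarks_period%d.tps", p))
    )
  }
  write_pedigree(st$pedigree, file.path(out_dir, "pedigree.csv"))
  utils::write.csv(st$phenotypes, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
  utils::write.csv(st$dam_traits, file.path(out_dir, "dam_traits.csv"), row.names = FALSE)
  truth <- st$truth
  truth$params <- unclass(truth$params)
  truth$params$designs <- lapply(truth$params$designs, function(d) d$matings)
  truth$params$mean_shape <- unclass(truth$params$mean_shape)
  truth$params$effect_basis <- lapply(truth$params$effect_basis, unclass)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(st)
}
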