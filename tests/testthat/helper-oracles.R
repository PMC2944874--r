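# Independent oracles and small fixture builders, kept deliberately naive:
# they re-derive expected values by brute force, by definition, or through a
# different library route than the implementation under test.

# --- kinship oracle ----------------------------------------------------------
# Coefficient-of-coancestry recursion f(i, j); A = 2 f off-diagonal and
# A[i, i] = 1 + f(sire_i, dam_i). Memoized recursion over labels; completely
# independent of the tabular method.
kinship_oracle <- function(ped) {
  id <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  names(sire) <- names(dam) <- id
  memo <- new.env()
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) {
      return(0)
    }
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    val <- if (a == b) {
      0.5 * (1 + f(sire[[a]], dam[[a]]))
    } else {
      # recurse on the individual appearing later in the pedigree
      ia <- match(a, id)
      ib <- match(b, id)
      if (ia < ib) {
        tmp <- a
        a <- b
        b <- tmp
      }
      0.5 * (f(sire[[a]], b) + f(dam[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      A[i, j] <- A[j, i] <- if (i == j) 1 + f(sire[[id[i]]], dam[[id[i]]]) else 2 * f(id[i], id[j])
    }
  }
  A
}

# Random valid pedigree with <= n_max individuals: founders plus offspring of
# randomly chosen earlier individuals.
random_pedigree <- function(n_max, seed) {
  set.seed(seed)
  n_founders <- sample(2:4, 1)
  n <- sample((n_founders + 1):n_max, 1)
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pair <- sample(seq_len(i - 1), 2, replace = FALSE)
    sire[i] <- id[pair[1]]
    dam[i] <- id[pair[2]]
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# --- restricted likelihood oracle -------------------------------------------
# Direct evaluation of the restricted log-likelihood with generic dense
# arithmetic (solve / determinant), no Cholesky reuse, no eigen rotation.
reml_oracle <- function(theta, y, X, Rlist) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (j in seq_along(Rlist)) V <- V + theta[j] * Rlist[[j]]
  Vi <- solve(V)
  W <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(W) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
    determinant(V, logarithm = TRUE)$modulus +
    determinant(W, logarithm = TRUE)$modulus +
    t(y) %*% P %*% y))
}

# --- landmark fixtures -------------------------------------------------------
# n random non-degenerate perturbations of the template salmonid shape, in
# long tibble form.
random_landmarks <- function(n, sd = 0.01, seed = 1, template = default_mean_shape()) {
  set.seed(seed)
  k <- nrow(template)
  purrr::map_dfr(seq_len(n), function(i) {
    X <- template + matrix(rnorm(2 * k, 0, sd), k, 2)
    tibble::tibble(id = sprintf("s%03d", i), landmark = seq_len(k), x = X[, 1], y = X[, 2])
  })
}

# Apply a random similarity transform to every specimen of a long tibble.
apply_similarity <- function(landmarks, seed) {
  set.seed(seed)
  landmarks |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      ang <- runif(1, -pi, pi)
      sc <- runif(1, 0.2, 5)
      tx <- runif(1, -10, 10)
      ty <- runif(1, -10, 10)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      XY <- sc * as.matrix(df[, c("x", "y")]) %*% t(R)
      df$x <- XY[, 1] + tx
      df$y <- XY[, 2] + ty
      df
    }) |>
    dplyr::ungroup()
}

# --- quantitative-genetic simulation helpers --------------------------------
# Offspring pedigree + A for the 30-family partial-factorial design.
assinica_pedigree <- function(offspring_per_family = 8) {
  d <- cross_design(15, 10, "partial_factorial", dams_per_sire = 3, sires_per_dam = 2)
  ped <- pedigree_from_design(d, offspring_per_family, strain = "assinica")
  list(ped = ped, A = additive_relationship(ped))
}

# Simulate one trait on the offspring of `ped` with the given components.
sim_trait <- function(ped, A, V_a, V_e, V_m = 0, seed = 1) {
  bv <- simulate_breeding_values(A, V_a, seed)
  set.seed(seed + 10^6)
  off <- dplyr::filter(ped, !is.na(.data$family))
  y <- bv[off$id] + rnorm(nrow(off), 0, sqrt(V_e))
  if (V_m > 0) {
    dams <- unique(off$dam)
    de <- setNames(rnorm(length(dams), 0, sqrt(V_m)), dams)
    y <- y + de[off$dam]
  }
  dplyr::mutate(off, y = unname(y))
}

# Sum of squared Procrustes distances to the consensus, computed directly.
procrustes_ss_of <- function(fit) {
  sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
}
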