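# REML animal model: variance components on a pedigree relationship matrix.
#
# The restricted log-likelihood maximized here is the standard
#   l(theta) = -1/2 [ (n - p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
# with V = sum_j theta_j R_j + theta_e I, P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1.
# Models with a single genetic term + residual use an exact eigen-rotation of
# the genetic covariance (diagonalize G once, O(n) per evaluation); models
# with dam/family terms use dense Cholesky algebra. Both paths evaluate the
# same likelihood; tests pin them to a brute-force dense-solve evaluation.

#' REML animal model for a single trait
#'
#' Estimates variance components of the animal model `y = Xb + Z a + (c) +
#' (f) + e` by restricted maximum likelihood, where the additive genetic
#' effects `a` have covariance `A V_a` given by the pedigree numerator
#' relationship matrix, optional dam effects `c` and full-sib family effects
#' `f` are iid, and `e` is residual. Heritability `h2 = V_a / V_p` and the
#' dam-effect ratio `m2 = V_m / V_p` are reported with delta-method standard
#' errors from a central-difference Hessian of the restricted likelihood.
#'
#' The optimizer is bound-constrained quasi-Newton (L-BFGS-B) on
#' log-variance parameters with three spread starting values; the best
#' restricted likelihood wins.
#'
#' @param data Data frame with one row per phenotyped individual, containing
#'   the trait, the id column and any fixed-effect / dam / family columns.
#' @param trait Name of the response column.
#' @param relationship Additive relationship matrix from
#'   [additive_relationship()]; must contain every phenotyped id.
#' @param fixed One-sided formula of fixed effects (default `~ 1`,
#'   population mean only). Reference-level coding; aliased columns are an
#'   error.
#' @param random Character subset of `c("additive", "dam", "family")`.
#' @param id,dam,family Column names in `data`.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @return An object of class `animal_model`: variance components (tibble),
#'   `h2`, `h2_se`, `m2`, `m2_se`, `loglik`, `fixed_estimates`, `converged`,
#'   `n`. Supports [tidy()] and [glance()].
#' @export
animal_model <- function(data, trait, relationship,
                         fixed = ~1,
                         random = "additive",
                         id = "id", dam = "dam", family = "family",
                         tol = 1e-8) {
  stopifnot(is.data.frame(data), trait %in% names(data))
  random <- match.arg(random, c("additive", "dam", "family"), several.ok = TRUE)
  data <- data[complete.cases(data[trait]), , drop = FALSE]
  y <- as.numeric(data[[trait]])
  n <- length(y)
  X <- fixed_design(fixed, data)
  if (n < ncol(X) + 2) stop_morphherit("too few observations for the fixed effects.")

  Rlist <- list()
  if ("additive" %in% random) {
    ids <- as.character(data[[id]])
    miss <- setdiff(ids, rownames(relationship))
    if (length(miss)) {
      stop_morphherit(sprintf(
        "phenotyped id(s) missing from relationship matrix: %s",
        paste(head(miss, 5), collapse = ", ")
      ))
    }
    Rlist$additive <- relationship[ids, ids]
  }
  if ("dam" %in% random) {
    Zd <- incidence(data[[dam]])
    Rlist$dam <- tcrossprod(Zd)
  }
  if ("family" %in% random) {
    check_family_confounding(data[[family]], data[[dam]])
    Zf <- incidence(data[[family]])
    Rlist$family <- tcrossprod(Zf)
  }

  fit <- reml_optimize(y, X, Rlist, tol = tol)
  theta <- fit$theta # named: random terms then "residual"
  vp <- sum(theta)
  ratios <- ratio_se(fit, theta)
  comp <- tibble::tibble(
    term = names(theta),
    variance = unname(theta)
  )
  structure(
    list(
      trait = trait, random = random, components = comp, V_p = vp,
      h2 = if ("additive" %in% random) unname(theta["additive"] / vp) else NA_real_,
      h2_se = ratios$h2_se,
      m2 = if ("dam" %in% random) unname(theta["dam"] / vp) else NA_real_,
      m2_se = ratios$m2_se,
      c2 = if ("family" %in% random) unname(theta["family"] / vp) else NA_real_,
      loglik = fit$loglik,
      fixed_estimates = fit$beta,
      converged = fit$converged,
      n = n,
      .refit = list(y = y, X = X, Rlist = Rlist, tol = tol)
    ),
    class = "animal_model"
  )
}

fixed_design <- function(fixed, data) {
  X <- stats::model.matrix(fixed, data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_morphherit(sprintf(
      "fixed-effect design is singular; aliased column(s): %s",
      paste(aliased, collapse = ", ")
    ))
  }
  X
}

incidence <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# A family term is inestimable when the family partition coincides with the
# dam partition (no split egg lots): Z_f is then collinear with the dam /
# sire-dam structure and family effects are completely confounded with the
# additive relationships.
check_family_confounding <- function(family, dam) {
  if (is.null(dam)) {
    return(invisible(TRUE))
  }
  tab <- table(as.character(family), as.character(dam))
  one_dam_per_family <- all(rowSums(tab > 0) == 1)
  one_family_per_dam <- all(colSums(tab > 0) == 1)
  if (one_dam_per_family && one_family_per_dam) {
    stop_morphherit(
      paste(
        "family effects are completely confounded with the dam / additive",
        "structure (no dam's eggs were split among sires); drop the family term."
      ),
      class = "morphherit_confounded_family"
    )
  }
  invisible(TRUE)
}

# ---- restricted likelihood machinery ---------------------------------------

# Dense evaluation of the restricted log-likelihood at variance components
# theta (vector over Rlist terms, then residual).
reml_loglik_dense <- function(theta, y, X, Rlist) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (j in seq_along(Rlist)) V <- V + theta[j] * Rlist[[j]]
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    return(list(loglik = -Inf, beta = rep(NA_real_, p)))
  }
  ldV <- 2 * sum(log(diag(L)))
  Viy <- backsolve(L, forwardsolve(t(L), y))
  ViX <- backsolve(L, forwardsolve(t(L), X))
  XtViX <- crossprod(X, ViX)
  cW <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cW)) {
    return(list(loglik = -Inf, beta = rep(NA_real_, p)))
  }
  ldW <- 2 * sum(log(diag(cW)))
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(cW, forwardsolve(t(cW), XtViy))
  yPy <- sum(y * Viy) - sum(XtViy * beta)
  list(
    loglik = -0.5 * ((n - p) * log(2 * pi) + ldV + ldW + yPy),
    beta = drop(beta)
  )
}

# Factory: returns function(theta) -> list(loglik, beta). Uses the eigen
# fast path when there is exactly one correlated term plus residual.
reml_loglik_fn <- function(y, X, Rlist) {
  n <- length(y)
  p <- ncol(X)
  if (length(Rlist) == 1) {
    eg <- eigen(Rlist[[1]], symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    U <- eg$vectors
    ys <- drop(crossprod(U, y))
    Xs <- crossprod(U, X)
    function(theta) {
      d <- theta[1] * lam + theta[2]
      if (any(d <= 0)) {
        return(list(loglik = -Inf, beta = rep(NA_real_, p)))
      }
      ldV <- sum(log(d))
      Xw <- Xs / d
      XtViX <- crossprod(Xs, Xw)
      cW <- tryCatch(chol(XtViX), error = function(e) NULL)
      if (is.null(cW)) {
        return(list(loglik = -Inf, beta = rep(NA_real_, p)))
      }
      XtViy <- crossprod(Xw, ys)
      beta <- backsolve(cW, forwardsolve(t(cW), XtViy))
      yPy <- sum(ys^2 / d) - sum(XtViy * beta)
      list(
        loglik = -0.5 * ((n - p) * log(2 * pi) + ldV +
          2 * sum(log(diag(cW))) + yPy),
        beta = drop(beta)
      )
    }
  } else {
    function(theta) reml_loglik_dense(theta, y, X, Rlist)
  }
}

reml_optimize <- function(y, X, Rlist, tol = 1e-8) {
  n_terms <- length(Rlist) + 1L
  nm <- c(names(Rlist), "residual")
  s2 <- var(stats::lm.fit(X, y)$residuals)
  if (!is.finite(s2) || s2 <= 0) s2 <- var(y) + 1e-12
  llfun <- reml_loglik_fn(y, X, Rlist)
  obj <- function(phi) {
    ll <- llfun(s2 * exp(phi))$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  k <- n_terms - 1L
  starts <- list(log(rep(1 / n_terms, n_terms)))
  if (k > 0) {
    starts <- c(
      starts,
      list(log(c(rep(0.05 / max(k, 1), k), 0.95))),
      list(log(c(rep(0.9 / k, k), 0.1)))
    )
  }
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    o <- tryCatch(
      optim(st, obj,
        method = "L-BFGS-B",
        lower = rep(-20, n_terms), upper = rep(6, n_terms),
        control = list(factr = tol / .Machine$double.eps, maxit = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10) {
      best <- o
      conv <- o$convergence == 0
    }
  }
  if (is.null(best)) stop_morphherit("REML optimization failed from all starting values.")
  theta <- setNames(s2 * exp(best$par), nm)
  # snap effectively-zero components to the boundary
  theta[theta < s2 * 1e-8] <- 0
  at <- llfun(pmax(theta, s2 * 1e-12))
  list(
    theta = theta, loglik = at$loglik,
    beta = setNames(at$beta, colnames(X)),
    converged = conv, llfun = llfun, scale = s2
  )
}

# Delta-method SEs of h2 and m2 from a central-difference Hessian of the
# restricted likelihood on the log-variance scale (step 1e-4).
ratio_se <- function(fit, theta) {
  nm <- names(theta)
  act <- which(theta > 0)
  out <- list(h2_se = NA_real_, m2_se = NA_real_)
  if (length(act) < 2) {
    return(out)
  }
  phi <- log(theta[act] / fit$scale)
  h <- 1e-4
  m <- length(phi)
  ll <- function(ph) {
    th <- theta
    th[act] <- fit$scale * exp(ph)
    fit$llfun(th)$loglik
  }
  H <- matrix(NA_real_, m, m)
  f0 <- ll(phi)
  for (i in seq_len(m)) {
    for (j in i:m) {
      ei <- ej <- rep(0, m)
      ei[i] <- h
      ej[j] <- h
      if (i == j) {
        H[i, i] <- (ll(phi + ei) - 2 * f0 + ll(phi - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (ll(phi + ei + ej) - ll(phi + ei - ej) -
            ll(phi - ei + ej) + ll(phi - ei - ej)) / (4 * h^2)
      }
    }
  }
  covphi <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(covphi) || any(diag(covphi) < 0)) {
    return(out)
  }
  vp <- sum(theta)
  ratio_grad <- function(term) {
    # d(theta_term / vp) / d phi_j = theta_j * (1{j==term} vp - theta_term)/vp^2
    tgt <- theta[act][term] / vp
    g <- -theta[act] * theta[act][term] / vp^2
    g[term] <- g[term] + theta[act][term] / vp
    g
  }
  se_of <- function(term_name) {
    pos <- match(term_name, nm[act])
    if (is.na(pos)) {
      return(NA_real_)
    }
    g <- ratio_grad(pos)
    sqrt(max(0, drop(t(g) %*% covphi %*% g)))
  }
  out$h2_se <- se_of("additive")
  out$m2_se <- se_of("dam")
  out
}

#' @method print animal_model
#' @export
print.animal_model <- function(x, ...) {
  cat(sprintf(
    "<animal_model: %s ~ [%s]; REML loglik %.3f%s>\n",
    x$trait, paste(x$random, collapse = " + "), x$loglik,
    if (x$converged) "" else " (NOT converged)"
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname animal_model
#' @param x An `animal_model` object.
#' @param ... Unused.
#' @method tidy animal_model
#' @export
tidy.animal_model <- function(x, ...) {
  comp <- dplyr::mutate(x$components, proportion = .data$variance / x$V_p)
  comp$se <- NA_real_
  comp$se[comp$term == "additive"] <- x$h2_se
  comp$se[comp$term == "dam"] <- x$m2_se
  comp
}

#' @rdname animal_model
#' @method glance animal_model
#' @export
glance.animal_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, loglik = x$loglik, V_p = x$V_p,
    h2 = x$h2, h2_se = x$h2_se, m2 = x$m2, m2_se = x$m2_se,
    converged = x$converged
  )
}

#' Likelihood-ratio test for a variance component
#'
#' Twice the difference in restricted log-likelihoods between a full model
#' and a reduced model with one random term dropped, clamped at zero when
#' the reduced model fits (numerically) better. P values are approximated
#' from a chi-square distribution with one degree of freedom; because the
#' null value lies on the boundary of the parameter space this is
#' conservative, and the 50:50 chi-square(0):chi-square(1) boundary mixture
#' is available via `boundary = TRUE`.
#'
#' @param full,reduced [animal_model()] fits on the same data; `reduced`
#'   must drop exactly one of `full`'s random terms.
#' @param boundary Use the 50:50 boundary mixture p-value.
#' @return A tibble with `statistic`, `df`, `p.value`, `dropped`.
#' @export
lrt_varcomp <- function(full, reduced, boundary = FALSE) {
  stopifnot(inherits(full, "animal_model"), inherits(reduced, "animal_model"))
  dropped <- setdiff(full$random, reduced$random)
  if (length(dropped) > 1 || length(setdiff(reduced$random, full$random)) != 0) {
    stop_morphherit("`reduced` must drop exactly one of `full`'s random terms.")
  }
  if (length(dropped) == 0) dropped <- NA_character_ # identical specs: statistic 0
  if (full$n != reduced$n || full$trait != reduced$trait) {
    stop_morphherit("full and reduced fits are not on the same data.")
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- lrt_pvalue(stat, boundary)
  tibble::tibble(statistic = stat, df = 1L, p.value = p, dropped = dropped)
}

lrt_pvalue <- function(stat, boundary = FALSE) {
  if (stat <= 0) {
    return(1)
  }
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) 0.5 * p else p
}

#' Drop one random term and refit
#'
#' Convenience refit for [lrt_varcomp()]: re-estimates the animal model
#' without `term`, reusing the stored response, design and covariance
#' structures.
#'
#' @param fit An [animal_model()] fit.
#' @param term Random term to drop (`"additive"`, `"dam"` or `"family"`).
#' @return An `animal_model` fit of the reduced model.
#' @export
drop_random_term <- function(fit, term) {
  stopifnot(inherits(fit, "animal_model"))
  term <- match.arg(term, fit$random)
  rf <- fit$.refit
  Rlist <- rf$Rlist[setdiff(names(rf$Rlist), term)]
  red <- reml_optimize(rf$y, rf$X, Rlist, tol = rf$tol)
  theta <- red$theta
  vp <- sum(theta)
  random <- setdiff(fit$random, term)
  structure(
    list(
      trait = fit$trait, random = random,
      components = tibble::tibble(term = names(theta), variance = unname(theta)),
      V_p = vp,
      h2 = if ("additive" %in% random) unname(theta["additive"] / vp) else NA_real_,
      h2_se = NA_real_,
      m2 = if ("dam" %in% random) unname(theta["dam"] / vp) else NA_real_,
      m2_se = NA_real_,
      c2 = if ("family" %in% random) unname(theta["family"] / vp) else NA_real_,
      loglik = red$loglik, fixed_estimates = red$beta,
      converged = red$converged, n = fit$n,
      .refit = list(y = rf$y, X = rf$X, Rlist = Rlist, tol = rf$tol)
    ),
    class = "animal_model"
  )
}
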