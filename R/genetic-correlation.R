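# Bivariate animal model: additive genetic covariance and correlation
# between two traits measured on the same individuals.
#
# With G = Z A Z' = U diag(lambda) U', the 2n x 2n covariance
#   V = Sigma_a (x) G + Sigma_e (x) I
# block-diagonalizes under the rotation I_2 (x) U' into n independent 2 x 2
# blocks M_i = lambda_i Sigma_a + Sigma_e, so each restricted-likelihood
# evaluation is O(n). Sigma_a and Sigma_e are kept positive definite by a
# log-sd / atanh-correlation parameterization.

bivar_loglik_fn <- function(y1, y2, X, G) {
  n <- length(y1)
  p <- ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  y1s <- drop(crossprod(U, y1))
  y2s <- drop(crossprod(U, y2))
  Xs <- crossprod(U, X)
  # theta = (Va1, Va2, cov_a, Ve1, Ve2, cov_e)
  function(theta) {
    a11 <- theta[1] * lam + theta[4]
    a22 <- theta[2] * lam + theta[5]
    a12 <- theta[3] * lam + theta[6]
    det2 <- a11 * a22 - a12^2
    if (any(det2 <= 0) || any(a11 <= 0)) {
      return(list(loglik = -Inf))
    }
    ldV <- sum(log(det2))
    # inverse of each 2x2 block
    i11 <- a22 / det2
    i22 <- a11 / det2
    i12 <- -a12 / det2
    # X'V^-1 X over the 2p x 2p bivariate design (I_2 (x) X)
    W11 <- crossprod(Xs, i11 * Xs)
    W22 <- crossprod(Xs, i22 * Xs)
    W12 <- crossprod(Xs, i12 * Xs)
    W <- rbind(cbind(W11, W12), cbind(W12, W22))
    cW <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(cW)) {
      return(list(loglik = -Inf))
    }
    Xty <- c(
      crossprod(Xs, i11 * y1s + i12 * y2s),
      crossprod(Xs, i12 * y1s + i22 * y2s)
    )
    beta <- backsolve(cW, forwardsolve(t(cW), Xty))
    yViy <- sum(i11 * y1s^2 + 2 * i12 * y1s * y2s + i22 * y2s^2)
    yPy <- yViy - sum(Xty * beta)
    list(
      loglik = -0.5 * ((2 * n - 2 * p) * log(2 * pi) + ldV +
        2 * sum(log(diag(cW))) + yPy),
      beta = beta
    )
  }
}

# parameter transform: phi = (log sa1, log sa2, z_a, log se1, log se2, z_e)
bivar_theta <- function(phi, fix_cov_a = FALSE) {
  sa1 <- exp(phi[1])
  sa2 <- exp(phi[2])
  ra <- if (fix_cov_a) 0 else tanh(phi[3])
  se1 <- exp(phi[4])
  se2 <- exp(phi[5])
  re <- tanh(phi[6])
  c(sa1^2, sa2^2, ra * sa1 * sa2, se1^2, se2^2, re * se1 * se2)
}

#' Additive genetic correlation between two traits
#'
#' Fits a bivariate REML animal model (additive + residual (co)variances) to
#' two traits measured on the same individuals, and tests the additive
#' covariance against zero by a likelihood-ratio test with one degree of
#' freedom (the constrained fit pins `cov_a = 0`). The genetic correlation
#' is `r_g = cov_a / sqrt(V_a1 V_a2)`; its standard error comes from the
#' delta method on a central-difference Hessian.
#'
#' @param data One row per individual; both trait columns and the id column.
#' @param trait1,trait2 Trait column names.
#' @param relationship Additive relationship matrix covering all ids.
#' @param fixed One-sided fixed-effects formula (shared by both traits).
#' @param id Id column name.
#' @param boundary Use the boundary-mixture p-value in the LRT (the plain
#'   chi-square(1) approximation is the default).
#' @return An object of class `genetic_correlation` with `r_g`, `se`,
#'   `cov_a`, the component estimates, `loglik`, and `lrt` (tibble).
#' @export
genetic_correlation <- function(data, trait1, trait2, relationship,
                                fixed = ~1, id = "id", boundary = FALSE) {
  stopifnot(all(c(trait1, trait2, id) %in% names(data)))
  keep <- complete.cases(data[c(trait1, trait2)])
  data <- data[keep, , drop = FALSE]
  y1 <- as.numeric(data[[trait1]])
  y2 <- as.numeric(data[[trait2]])
  X <- fixed_design(fixed, data)
  ids <- as.character(data[[id]])
  G <- relationship[ids, ids]
  llfun <- bivar_loglik_fn(y1, y2, X, G)

  # starting values from univariate fits
  u1 <- reml_optimize(y1, X, list(additive = G))
  u2 <- reml_optimize(y2, X, list(additive = G))
  base <- c(
    0.5 * log(pmax(u1$theta["additive"], 1e-8 * var(y1))),
    0.5 * log(pmax(u2$theta["additive"], 1e-8 * var(y2))),
    0,
    0.5 * log(pmax(u1$theta["residual"], 1e-8 * var(y1))),
    0.5 * log(pmax(u2$theta["residual"], 1e-8 * var(y2))),
    0
  )
  fit_biv <- function(fix_cov_a) {
    obj <- function(phi) {
      ll <- llfun(bivar_theta(phi, fix_cov_a))$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    starts <- list(base, base + c(0, 0, atanh(0.5), 0, 0, 0))
    if (fix_cov_a) starts <- list(base)
    best <- NULL
    for (st in starts) {
      o <- tryCatch(
        optim(st, obj,
          method = "L-BFGS-B",
          lower = c(-15, -15, -5, -15, -15, -5),
          upper = c(8, 8, 5, 8, 8, 5),
          control = list(maxit = 300)
        ),
        error = function(e) NULL
      )
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop_morphherit("bivariate REML optimization failed.")
    best
  }
  full <- fit_biv(FALSE)
  red <- fit_biv(TRUE)
  theta <- bivar_theta(full$par, FALSE)
  names(theta) <- c("V_a1", "V_a2", "cov_a", "V_e1", "V_e2", "cov_e")
  r_g <- tanh(full$par[3])
  # SE of r_g: delta method on z = atanh(r_g)
  h <- 1e-4
  llz <- function(z) {
    ph <- full$par
    ph[3] <- z
    llfun(bivar_theta(ph, FALSE))$loglik
  }
  z <- full$par[3]
  d2 <- (llz(z + h) - 2 * llz(z) + llz(z - h)) / h^2
  se <- if (is.finite(d2) && d2 < 0) (1 - r_g^2) * sqrt(-1 / d2) else NA_real_
  stat <- max(0, 2 * (-full$value + red$value))
  lrt <- tibble::tibble(
    statistic = stat, df = 1L,
    p.value = lrt_pvalue(stat, boundary), dropped = "cov_a"
  )
  structure(
    list(
      traits = c(trait1, trait2), components = theta,
      cov_a = unname(theta["cov_a"]), r_g = unname(r_g), se = se,
      loglik = -full$value, loglik_constrained = -red$value,
      lrt = lrt, n = length(y1)
    ),
    class = "genetic_correlation"
  )
}

#' @method print genetic_correlation
#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf(
    "<genetic_correlation: %s ~ %s, r_g = %.3f (SE %.3f), LRT p = %.4g>\n",
    x$traits[1], x$traits[2], x$r_g, x$se, x$lrt$p.value
  ))
  invisible(x)
}

#' @rdname genetic_correlation
#' @param x A `genetic_correlation` object.
#' @param ... Unused.
#' @method tidy genetic_correlation
#' @export
tidy.genetic_correlation <- function(x, ...) {
  tibble::tibble(
    term = names(x$components),
    estimate = unname(x$components)
  )
}

#' @rdname genetic_correlation
#' @method glance genetic_correlation
#' @export
glance.genetic_correlation <- function(x, ...) {
  tibble::tibble(
    n = x$n, r_g = x$r_g, se = x$se, cov_a = x$cov_a,
    loglik = x$loglik, lrt_statistic = x$lrt$statistic,
    lrt_p = x$lrt$p.value
  )
}
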