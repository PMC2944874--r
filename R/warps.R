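#' Thin-plate-spline warp basis from a consensus shape
#'
#' Builds the bending energy matrix of the thin-plate spline interpolant
#' anchored at the consensus landmarks (kernel `U(r) = r^2 log r^2`; the
#' bending energy matrix is the upper-left k x k block of the inverted TPS
#' system) and its eigenvectors, the principal warps. In two dimensions
#' exactly `k - 3` eigenvalues are nonzero; affine transforms of the
#' consensus lie in the null space. The two-dimensional uniform (affine)
#' shape basis is the orthogonal complement of the similarity directions
#' within the affine subspace at the consensus.
#'
#' @param consensus k x 2 matrix, typically `gpa()$consensus` (centered,
#'   unit centroid size).
#' @param alpha Relative-warp weighting exponent: principal-warp projections
#'   are weighted by `eigenvalue^(-alpha/2)` when `alpha != 0`. The default
#'   0 weights all warps equally.
#' @return An object of class `warp_basis` with `bending_energy` (k x k),
#'   `principal_warps` (k x (k-3) orthonormal columns, decreasing bending
#'   energy), `eigenvalues`, `uniform_basis` (2k x 2 orthonormal columns in
#'   `vec(k x 2)` layout), `consensus`, `alpha`.
#' @export
warp_basis <- function(consensus, alpha = 0) {
  stopifnot(is.matrix(consensus), ncol(consensus) == 2)
  k <- nrow(consensus)
  if (k < 4) stop_morphherit("warp basis requires at least 4 landmarks.")
  D2 <- as.matrix(stats::dist(consensus))^2
  K <- ifelse(D2 > 0, D2 * log(D2), 0)
  Q <- cbind(1, consensus)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- tryCatch(solve(L), error = function(e) {
    stop_morphherit("singular thin-plate-spline system (collinear landmarks?).")
  })
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  Be <- (Be + t(Be)) / 2
  eb <- eigen(Be, symmetric = TRUE)
  nz <- which(eb$values > 1e-10 * max(eb$values))
  if (length(nz) != k - 3) {
    rlang::warn(sprintf(
      "bending energy matrix has %d nonzero eigenvalues; expected k - 3 = %d.",
      length(nz), k - 3
    ))
  }
  pw <- eb$vectors[, nz, drop = FALSE] # decreasing eigenvalue order
  ev <- eb$values[nz]

  # uniform basis: affine directions X B' minus the similarity directions
  X <- sweep(consensus, 2, colMeans(consensus))
  aff <- sapply(
    list(
      matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 1, 0), 2),
      matrix(c(0, 1, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)
    ),
    function(B) as.vector(X %*% t(B))
  )
  sim <- cbind(as.vector(X), as.vector(X %*% t(matrix(c(0, -1, 1, 0), 2))))
  sim <- qr.Q(qr(sim))
  aff <- aff - sim %*% crossprod(sim, aff)
  qa <- qr(aff)
  U <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
  if (ncol(U) != 2) {
    stop_morphherit("uniform shape subspace is not two-dimensional (degenerate consensus).")
  }
  structure(
    list(
      bending_energy = Be, principal_warps = pw, eigenvalues = ev,
      uniform_basis = U, consensus = consensus, alpha = alpha
    ),
    class = "warp_basis"
  )
}

#' Partial and relative warp scores
#'
#' Projects each aligned specimen's deviation from the consensus onto the
#' principal warps (x and y components per warp, weighted by
#' `eigenvalue^(-alpha/2)` when `alpha != 0`) and onto the two uniform
#' (affine) basis vectors, giving `2k - 4` partial warp scores per specimen.
#' A singular value decomposition of the centered partial-warp score matrix
#' then yields the relative warp scores: orthogonal axes of shape variation
#' ordered by decreasing variance explained. With `alpha = 0` the relative
#' warps equal the principal components of the aligned coordinates
#' themselves. Each relative-warp axis is oriented so that its
#' largest-magnitude loading is positive, making signs deterministic.
#'
#' @param fit A [gpa()] result.
#' @param basis A [warp_basis()] built from `fit$consensus`; computed
#'   automatically when omitted.
#' @return An object of class `warp_scores` with `partial` (tibble: `id` +
#'   score columns `pw1x, pw1y, ..., uni1, uni2`), `relative` (tibble: `id` +
#'   `rw1..rw(2k-4)`), `variance_fraction` (per relative warp), `loadings`
#'   (in the partial-warp basis), `loadings_shape` (the same loadings mapped
#'   into landmark space, `vec(k x 2)` layout), `n_axes` (number of
#'   relative-warp axes), `basis`.
#' @export
warp_scores <- function(fit, basis = NULL) {
  stopifnot(inherits(fit, "gpa"))
  basis <- basis %||% warp_basis(fit$consensus)
  if (!isTRUE(all.equal(basis$consensus, fit$consensus, tolerance = 1e-8))) {
    stop_morphherit("warp basis was not built from this GPA's consensus.")
  }
  arr <- fit$aligned
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  ids <- dimnames(arr)[[3]]
  dev <- matrix(0, n, 2 * k) # vec(k x 2) per row
  for (i in seq_len(n)) dev[i, ] <- as.vector(arr[, , i] - fit$consensus)
  pw <- basis$principal_warps
  m <- ncol(pw)
  # projection matrix from vec(k x 2) deviations to partial-warp scores:
  # x and y component per principal warp, then the two uniform vectors
  proj <- matrix(0, 2 * k, 2 * m + 2)
  w <- if (basis$alpha != 0) basis$eigenvalues^(-basis$alpha / 2) else rep(1, m)
  for (j in seq_len(m)) {
    proj[seq_len(k), 2 * j - 1] <- w[j] * pw[, j]
    proj[k + seq_len(k), 2 * j] <- w[j] * pw[, j]
  }
  proj[, 2 * m + 1:2] <- basis$uniform_basis
  partial <- dev %*% proj
  colnames(partial) <- c(
    paste0("pw", rep(seq_len(m), each = 2), c("x", "y")),
    c("uni1", "uni2")
  )
  p <- ncol(partial) # 2k - 4
  if (n <= p) {
    rlang::warn(sprintf(
      "only %d specimens for %d warp axes; trailing relative warps have zero variance.",
      n, p
    ))
  }
  ctr <- colMeans(partial)
  centered <- sweep(partial, 2, ctr)
  sv <- svd(centered)
  load <- sv$v
  # sign convention applied to the loadings mapped back into landmark space,
  # so signs do not depend on the arbitrary orientation of principal warps
  # inside degenerate bending-energy eigenspaces
  shape_load <- proj %*% load
  for (j in seq_len(ncol(load))) {
    if (shape_load[which.max(abs(shape_load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rel <- centered %*% load
  colnames(rel) <- paste0("rw", seq_len(ncol(rel)))
  varfrac <- apply(rel, 2, var)
  varfrac <- varfrac / sum(varfrac)
  structure(
    list(
      partial = tibble::tibble(id = ids, tibble::as_tibble(partial)),
      relative = tibble::tibble(id = ids, tibble::as_tibble(rel)),
      variance_fraction = varfrac,
      loadings = load,
      loadings_shape = proj %*% load,
      n_axes = ncol(rel),
      basis = basis
    ),
    class = "warp_scores"
  )
}

#' @method print warp_scores
#' @export
print.warp_scores <- function(x, ...) {
  cat(sprintf(
    "<warp_scores: %d specimens, %d axes; leading variance fractions %s>\n",
    nrow(x$relative), x$n_axes,
    paste(sprintf("%.3f", head(x$variance_fraction, 4)), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname warp_scores
#' @param x A `warp_scores` object.
#' @param type `"relative"` (default) or `"partial"`.
#' @param ... Unused.
#' @method tidy warp_scores
#' @export
tidy.warp_scores <- function(x, type = c("relative", "partial"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @rdname warp_scores
#' @method glance warp_scores
#' @export
glance.warp_scores <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$relative), n_axes = x$n_axes,
    var_rw1 = x$variance_fraction[1],
    var_rw6_cum = sum(head(x$variance_fraction, 6))
  )
}

#' Relative warps analysis in one call
#'
#' Convenience wrapper chaining [gpa()], [warp_basis()] and [warp_scores()].
#'
#' @inheritParams gpa
#' @inheritParams warp_basis
#' @return A `warp_scores` object with the `gpa` fit attached as `$gpa`.
#' @export
relative_warps <- function(landmarks, alpha = 0, tol = 1e-10, max_iter = 100L) {
  fit <- gpa(landmarks, tol = tol, max_iter = max_iter)
  ws <- warp_scores(fit, warp_basis(fit$consensus, alpha = alpha))
  ws$gpa <- fit
  ws
}

#' Project aligned specimens onto a reference shape direction
#'
#' Scores each superimposed specimen on a fixed deformation direction
#' defined relative to a template shape (for example, the generating basis
#' of a simulation): the template is rotated onto the GPA consensus by
#' ordinary Procrustes rotation, the direction is carried along, and each
#' specimen's deviation from the consensus is projected onto it. Useful for
#' parameter-recovery checks where the estimated warp axes need not align
#' exactly with the generating directions.
#'
#' @param fit A [gpa()] result.
#' @param direction k x 2 matrix: a unit deformation direction at the
#'   template.
#' @param template k x 2 matrix the direction is expressed at (centered,
#'   unit centroid size), e.g. [default_mean_shape()].
#' @return A tibble with columns `id` and `score`.
#' @export
project_shape_direction <- function(fit, direction, template) {
  stopifnot(inherits(fit, "gpa"))
  Xc <- sweep(template, 2, colMeans(template))
  Xc <- Xc / sqrt(sum(Xc^2))
  s <- svd(crossprod(Xc, fit$consensus))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  dir_rot <- direction %*% t(R)
  n <- dim(fit$aligned)[3]
  score <- vapply(seq_len(n), function(i) {
    sum((fit$aligned[, , i] - fit$consensus) * dir_rot)
  }, 0)
  tibble::tibble(id = dimnames(fit$aligned)[[3]], score = score)
}
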