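#' Centroid size of landmark configurations
#'
#' Centroid size is computed as the square root of the summed squared
#' distances of a configuration's landmarks from their centroid — the
#' standard geometric-morphometric size measure. (The equivalent
#' formulation via summed squared inter-landmark distances differs only by
#' the constant factor `sqrt(k)` for fixed landmark number `k` and yields
#' identical shape variables.) Centroid size scales linearly under uniform
#' scaling and is invariant to rotation and translation.
#'
#' @param landmarks Long-format landmark tibble (`id`, `landmark`, `x`, `y`),
#'   one or many specimens.
#' @return A tibble with columns `id` and `csize`.
#' @examples
#' sq <- tibble::tibble(
#'   id = "sq", landmark = 1:4,
#'   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)
#' )
#' centroid_size(sq)$csize # sqrt(2)
#' @export
centroid_size <- function(landmarks) {
  arr <- landmarks_to_array(landmarks)
  cs <- apply(arr, 3, centroid_size_one)
  tibble::tibble(id = dimnames(arr)[[3]], csize = unname(cs))
}

centroid_size_one <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(Xc^2))
  if (cs < 1e-12) {
    stop_morphherit("degenerate configuration: all landmarks coincide.")
  }
  cs
}

# Rotate configuration X (centered) onto reference Y (centered) by the
# orthogonal Procrustes rotation with determinant +1 (no reflection).
procrustes_rotate <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  X %*% t(R)
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes landmark configurations to remove variation due
#' to location, orientation and scale: each configuration is centered,
#' scaled to unit centroid size, and rotated onto the current consensus by
#' the least-squares orthogonal rotation; the consensus (mean shape) is
#' recomputed and the cycle repeats until its displacement falls below
#' `tol`. This is partial Procrustes superimposition: aligned configurations
#' keep unit centroid size (no extra scaling during rotation), matching the
#' defaults of the standard relative-warps software. The converged solution
#' is rotated so the consensus lies along its own principal axes, making the
#' output orientation deterministic.
#'
#' @param landmarks Long-format landmark tibble; >= 2 specimens, all with the
#'   same number of landmarks.
#' @param tol Convergence tolerance on root-mean-square consensus
#'   displacement between iterations.
#' @param max_iter Maximum number of alignment sweeps; if reached without
#'   convergence the result is returned with `converged = FALSE` and a
#'   warning.
#' @return An object of class `gpa` with elements `consensus` (k x 2
#'   matrix), `aligned` (k x 2 x n array), `centroid_sizes` (tibble `id`,
#'   `csize` in input units), `iterations`, `converged`. Use [tidy()] for a
#'   long tibble of aligned coordinates.
#' @export
gpa <- function(landmarks, tol = 1e-10, max_iter = 100L) {
  arr <- landmarks_to_array(landmarks)
  n <- dim(arr)[3]
  if (n < 2) stop_morphherit("GPA requires at least two configurations.")
  cs <- apply(arr, 3, centroid_size_one)
  # center and scale to unit centroid size
  for (i in seq_len(n)) {
    Xc <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    arr[, , i] <- Xc / sqrt(sum(Xc^2))
  }
  consensus <- arr[, , 1]
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      arr[, , i] <- procrustes_rotate(arr[, , i], consensus)
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf("GPA did not converge in %d iterations.", max_iter))
  }
  # deterministic orientation: principal axes of the consensus, with the
  # leading axis pointing toward the landmark of largest |x| (180-degree fix)
  pc <- eigen(cov(consensus), symmetric = TRUE)$vectors
  if (det(pc) < 0) pc[, 2] <- -pc[, 2]
  rot <- function(X) X %*% pc
  consensus <- rot(consensus)
  if (consensus[which.max(abs(consensus[, 1])), 1] < 0) {
    consensus <- -consensus # 180-degree rotation in 2D
    flip <- TRUE
  } else {
    flip <- FALSE
  }
  for (i in seq_len(n)) {
    arr[, , i] <- rot(arr[, , i])
    if (flip) arr[, , i] <- -arr[, , i]
  }
  structure(
    list(
      consensus = consensus,
      aligned = arr,
      centroid_sizes = tibble::tibble(id = dimnames(arr)[[3]], csize = unname(cs)),
      iterations = iter,
      converged = converged
    ),
    class = "gpa"
  )
}

#' @method print gpa
#' @export
print.gpa <- function(x, ...) {
  cat(sprintf(
    "<gpa: %d specimens, %d landmarks, %d iteration(s), %s>\n",
    dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @rdname gpa
#' @param x A `gpa` object.
#' @param ... Unused.
#' @method tidy gpa
#' @export
tidy.gpa <- function(x, ...) {
  dplyr::left_join(array_to_landmarks(x$aligned), x$centroid_sizes, by = "id")
}

# Sum of squared Procrustes distances of aligned configurations to the
# consensus (monitoring / test hook).
procrustes_ss <- function(fit) {
  sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
}
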