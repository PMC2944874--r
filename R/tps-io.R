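#' Read landmark configurations from a TPS file
#'
#' Parses the de facto standard TPS landmark format: each record starts with
#' `LM=<k>`, followed by `k` lines of `x y` coordinates and optional `ID=`,
#' `IMAGE=` and `SCALE=` lines. When `SCALE=` is present the coordinates are
#' multiplied by it so stored values are in physical units.
#'
#' @param path Path to a TPS file.
#' @return A tibble in long format with columns `id` (specimen label,
#'   falling back to `IMAGE=` then to a running index when no `ID=` record
#'   is present), `landmark` (1..k), `x`, `y`.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    rlang::warn(sprintf("TPS file '%s' contains no records.", path))
    return(tibble::tibble(
      id = character(), landmark = integer(),
      x = double(), y = double()
    ))
  }
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts) || starts[1] != 1) {
    stop_morphherit(sprintf("TPS file '%s' does not start with an LM= record.", path))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    coord_lines <- block[-1][!grepl("=", block[-1], fixed = TRUE)]
    if (length(coord_lines) != k) {
      stop_morphherit(sprintf(
        "TPS record %d declares LM=%d but has %d coordinate lines.",
        r, k, length(coord_lines)
      ), class = "morphherit_parse_error")
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (any(!is.finite(xy)) || ncol(xy) != 2) {
      stop_morphherit(sprintf("TPS record %d has malformed coordinates.", r),
        class = "morphherit_parse_error"
      )
    }
    keyed <- block[grepl("=", block, fixed = TRUE)][-1]
    get_key <- function(key) {
      m <- grep(paste0("^", key, "\\s*="), keyed, ignore.case = TRUE, value = TRUE)
      if (length(m)) sub(paste0("^", key, "\\s*=\\s*"), "", m[1], ignore.case = TRUE) else NA_character_
    }
    id <- get_key("ID")
    if (is.na(id)) id <- get_key("IMAGE")
    if (is.na(id)) id <- sprintf("specimen_%d", r)
    scale <- suppressWarnings(as.numeric(get_key("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    out[[r]] <- tibble::tibble(
      id = id, landmark = seq_len(k),
      x = xy[, 1], y = xy[, 2]
    )
  }
  dplyr::bind_rows(out)
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: `read_tps(write_tps(x, path))` reproduces `x` to
#' full double precision. No `SCALE=` records are emitted (coordinates are
#' written as stored).
#'
#' @param landmarks Long-format landmark tibble (`id`, `landmark`, `x`, `y`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(landmarks, path) {
  check_landmarks(landmarks)
  recs <- split(landmarks, factor(landmarks$id, levels = unique(landmarks$id)))
  con <- file(path, "w")
  on.exit(close(con))
  for (df in recs) {
    df <- df[order(df$landmark), ]
    writeLines(sprintf("LM=%d", nrow(df)), con)
    writeLines(sprintf("%.17g %.17g", df$x, df$y), con)
    writeLines(sprintf("ID=%s", df$id[1]), con)
  }
  invisible(path)
}

# Validate a long-format landmark tibble: equal k per specimen, finite
# coordinates, no coincident landmarks.
check_landmarks <- function(landmarks, min_k = 4L) {
  stopifnot(is.data.frame(landmarks))
  need <- c("id", "landmark", "x", "y")
  if (!all(need %in% names(landmarks))) {
    stop_morphherit(sprintf(
      "landmark data must have columns %s.",
      paste(need, collapse = ", ")
    ))
  }
  ks <- table(landmarks$id)
  if (length(unique(as.integer(ks))) > 1) {
    stop_morphherit("all specimens must have the same number of landmarks.")
  }
  if (any(!is.finite(landmarks$x)) || any(!is.finite(landmarks$y))) {
    stop_morphherit("landmark coordinates must be finite.")
  }
  invisible(landmarks)
}

# Long tibble -> k x 2 x n array (specimen order = first appearance).
landmarks_to_array <- function(landmarks) {
  check_landmarks(landmarks)
  ids <- unique(landmarks$id)
  k <- sum(landmarks$id == ids[1])
  arr <- array(NA_real_, dim = c(k, 2, length(ids)), dimnames = list(NULL, c("x", "y"), ids))
  df <- landmarks[order(match(landmarks$id, ids), landmarks$landmark), ]
  arr[, 1, ] <- matrix(df$x, nrow = k)
  arr[, 2, ] <- matrix(df$y, nrow = k)
  arr
}

# k x 2 x n array -> long tibble.
array_to_landmarks <- function(arr) {
  ids <- dimnames(arr)[[3]] %||% sprintf("specimen_%d", seq_len(dim(arr)[3]))
  k <- dim(arr)[1]
  tibble::tibble(
    id = rep(ids, each = k),
    landmark = rep(seq_len(k), times = length(ids)),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ])
  )
}
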