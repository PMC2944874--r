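#' Construct a half-sib mating design
#'
#' Builds the list of sire x dam matings for the breeding designs used in
#' salmonid common-garden heritability experiments: full-sib families nested
#' within half-sib sire groups (`"nested"`), partial factorials in which each
#' dam is also mated to several sires (`"partial_factorial"`), and nested
#' designs in which the egg lots of some dams are split and fertilized by a
#' second sire (`"split_egg_lot"`).
#'
#' Partner assignment is deterministic by label order unless `seed` is given,
#' in which case dams are randomly permuted before assignment. Family counts
#' are invariant to the assignment.
#'
#' @param n_dams,n_sires Number of female and male parents.
#' @param kind Design kind: `"nested"`, `"partial_factorial"` or
#'   `"split_egg_lot"`.
#' @param dams_per_sire For nested/split designs, an allowed range (length-2
#'   vector) of dams mated to each sire; default `c(2, 3)`. For a partial
#'   factorial, the exact number of dams per sire.
#' @param sires_per_dam Partial factorial only: number of sires each dam is
#'   mated to.
#' @param n_split_dams Split-egg-lot only: how many dams have their eggs
#'   fertilized by a second sire.
#' @param dam_prefix,sire_prefix Label prefixes for generated parent ids.
#' @param seed Optional integer; randomizes which dams pair with which sires.
#'
#' @return A `cross_design` object: a list with `matings` (tibble with
#'   columns `sire`, `dam`, `family`), `n_dams`, `n_sires`, `kind` and
#'   `n_families`.
#'
#' @examples
#' # 12 females x 5 males, each sire taking 2-3 dams -> 12 families
#' cross_design(12, 5, "nested")
#' # 15 dams x 10 sires, sire x 3 dams, dam x 2 sires -> 30 families
#' cross_design(15, 10, "partial_factorial",
#'   dams_per_sire = 3, sires_per_dam = 2
#' )
#' @export
cross_design <- function(n_dams, n_sires,
                         kind = c("nested", "partial_factorial", "split_egg_lot"),
                         dams_per_sire = NULL, sires_per_dam = NULL,
                         n_split_dams = 0L,
                         dam_prefix = "D", sire_prefix = "S",
                         seed = NULL) {
  n_dams <- check_count(n_dams, "n_dams")
  n_sires <- check_count(n_sires, "n_sires")
  kind <- match.arg(kind)
  dams <- sprintf("%s%02d", dam_prefix, seq_len(n_dams))
  sires <- sprintf("%s%02d", sire_prefix, seq_len(n_sires))
  if (!is.null(seed)) {
    dams <- with_seed(seed, sample(dams))
  }

  matings <- switch(kind,
    nested = design_nested(dams, sires, dams_per_sire %||% c(2, 3)),
    partial_factorial = design_partial_factorial(
      dams, sires,
      dams_per_sire %||% stop_morphherit(
        "`dams_per_sire` is required for a partial factorial design.",
        class = "morphherit_infeasible_design"
      ),
      sires_per_dam %||% stop_morphherit(
        "`sires_per_dam` is required for a partial factorial design.",
        class = "morphherit_infeasible_design"
      )
    ),
    split_egg_lot = design_split_egg_lot(
      dams, sires, dams_per_sire %||% c(2, 3),
      check_count(n_split_dams, "n_split_dams")
    )
  )
  if (anyDuplicated(matings[c("sire", "dam")]) > 0) {
    stop_morphherit("duplicate sire x dam mating produced; design rule infeasible.",
      class = "morphherit_infeasible_design"
    )
  }
  matings$family <- sprintf("F%03d", seq_len(nrow(matings)))
  structure(
    list(
      matings = tibble::as_tibble(matings[c("sire", "dam", "family")]),
      n_dams = n_dams, n_sires = n_sires, kind = kind,
      n_families = nrow(matings)
    ),
    class = "cross_design"
  )
}

# Each dam has exactly one sire; sires take between lo and hi dams.
design_nested <- function(dams, sires, dams_per_sire) {
  lo <- dams_per_sire[1]
  hi <- dams_per_sire[length(dams_per_sire)]
  nd <- length(dams)
  ns <- length(sires)
  if (nd < ns * lo || nd > ns * hi) {
    stop_morphherit(
      sprintf(
        "infeasible nested design: %d dams cannot be split among %d sires taking %d-%d dams each.",
        nd, ns, lo, hi
      ),
      class = "morphherit_infeasible_design"
    )
  }
  base <- nd %/% ns
  extra <- nd %% ns
  counts <- rep(base, ns)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  data.frame(
    sire = rep(sires, counts),
    dam = dams,
    stringsAsFactors = FALSE
  )
}

# Each sire mated to `s` dams, each dam to `d` sires; requires ns*s == nd*d.
design_partial_factorial <- function(dams, sires, dams_per_sire, sires_per_dam) {
  s <- check_count(dams_per_sire, "dams_per_sire")
  d <- check_count(sires_per_dam, "sires_per_dam")
  nd <- length(dams)
  ns <- length(sires)
  if (ns * s != nd * d) {
    stop_morphherit(
      sprintf(
        "infeasible partial factorial: %d sires x %d dams each = %d matings but %d dams x %d sires each = %d.",
        ns, s, ns * s, nd, d, nd * d
      ),
      class = "morphherit_infeasible_design"
    )
  }
  if (s > nd) {
    stop_morphherit("infeasible partial factorial: a sire cannot take more dams than exist.",
      class = "morphherit_infeasible_design"
    )
  }
  n_mat <- ns * s
  data.frame(
    sire = rep(sires, each = s),
    dam = dams[((seq_len(n_mat) - 1L) %% nd) + 1L],
    stringsAsFactors = FALSE
  )
}

# Nested base assignment; the first n_split dams get a second sire drawn from
# the sires with spare capacity, keeping every sire within the allowed range.
design_split_egg_lot <- function(dams, sires, dams_per_sire, n_split) {
  lo <- dams_per_sire[1]
  hi <- dams_per_sire[length(dams_per_sire)]
  nd <- length(dams)
  ns <- length(sires)
  if (n_split > nd) {
    stop_morphherit("cannot split more egg lots than there are dams.",
      class = "morphherit_infeasible_design"
    )
  }
  n_mat <- nd + n_split
  if (n_mat < ns * lo || n_mat > ns * hi) {
    stop_morphherit(
      sprintf(
        "infeasible split-egg-lot design: %d matings cannot be spread over %d sires taking %d-%d dams each.",
        n_mat, ns, lo, hi
      ),
      class = "morphherit_infeasible_design"
    )
  }
  # primary assignment: distribute all dams over sires as evenly as possible
  base <- nd %/% ns
  extra <- nd %% ns
  counts <- rep(base, ns)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  primary_sire <- rep(seq_len(ns), counts)
  # second sires: walk sires from the last label backwards, skipping a dam's
  # primary sire and any sire already at capacity `hi`
  load <- counts
  second <- integer(n_split)
  cand <- rev(seq_len(ns))
  ci <- 1L
  for (j in seq_len(n_split)) {
    tries <- 0L
    repeat {
      s <- cand[((ci - 1L) %% ns) + 1L]
      ci <- ci + 1L
      tries <- tries + 1L
      if (s != primary_sire[j] && load[s] < hi) break
      if (tries > 2L * ns) {
        stop_morphherit("infeasible split-egg-lot design: no sire available for a split lot.",
          class = "morphherit_infeasible_design"
        )
      }
    }
    second[j] <- s
    load[s] <- load[s] + 1L
  }
  data.frame(
    sire = sires[c(primary_sire, second)],
    dam = dams[c(seq_len(nd), seq_len(n_split))],
    stringsAsFactors = FALSE
  )
}

#' @method print cross_design
#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf(
    "<cross_design: %s, %d dams x %d sires, %d families>\n",
    x$kind, x$n_dams, x$n_sires, x$n_families
  ))
  print(x$matings, n = 6)
  invisible(x)
}

#' Expand a mating design into a pedigree table
#'
#' Founders (all dams and sires, unknown parents) are listed first, followed
#' by `offspring_per_family` offspring for each family, so the result is
#' topologically ordered (parents precede offspring).
#'
#' @param design A [cross_design()] object.
#' @param offspring_per_family Offspring records per family (>= 1).
#' @param strain Strain label attached to every record.
#' @return A tibble with columns `id`, `sire`, `dam`, `strain`, `family`,
#'   `generation`. Unknown parents are `NA`.
#' @export
pedigree_from_design <- function(design, offspring_per_family, strain = "A") {
  stopifnot(inherits(design, "cross_design"))
  k <- check_count(offspring_per_family, "offspring_per_family")
  m <- design$matings
  founders <- tibble::tibble(
    id = paste0(strain, "_", c(unique(m$sire), unique(m$dam))),
    sire = NA_character_, dam = NA_character_,
    strain = strain, family = NA_character_, generation = 0L
  )
  off <- tidyr::expand_grid(fam_row = seq_len(nrow(m)), rep = seq_len(k))
  offspring <- tibble::tibble(
    id = sprintf("%s_%s_%02d", strain, m$family[off$fam_row], off$rep),
    sire = paste0(strain, "_", m$sire[off$fam_row]),
    dam = paste0(strain, "_", m$dam[off$fam_row]),
    strain = strain,
    family = paste0(strain, "_", m$family[off$fam_row]),
    generation = 1L
  )
  dplyr::bind_rows(founders, offspring)
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Computes the additive genetic relationship matrix A by the tabular method:
#' `A[i,i] = 1 + F_i` where the inbreeding coefficient `F_i` is half the
#' relationship between i's parents, and `A[i,j] = (A[j,sire_i] +
#' A[j,dam_i]) / 2` for j preceding i. Unknown parents are treated as
#' unrelated, non-inbred founders.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (`NA` for
#'   unknown parents), topologically ordered so parents precede offspring.
#' @return A symmetric positive semidefinite matrix with `id` dimnames, in
#'   pedigree order.
#' @examples
#' ped <- tibble::tibble(
#'   id = c("s", "d", "o"),
#'   sire = c(NA, NA, "s"), dam = c(NA, NA, "d")
#' )
#' additive_relationship(ped)["s", "o"] # 0.5
#' @export
additive_relationship <- function(pedigree) {
  stopifnot(is.data.frame(pedigree), all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) {
    stop_morphherit("duplicate individual ids in pedigree.")
  }
  n <- length(id)
  idx <- function(lab) match(lab, id)
  si <- idx(as.character(pedigree$sire))
  di <- idx(as.character(pedigree$dam))
  bad <- which(!is.na(pedigree$sire) & is.na(si))
  if (length(bad)) {
    stop_morphherit(sprintf(
      "sire label(s) not found in pedigree: %s",
      paste(unique(pedigree$sire[bad]), collapse = ", ")
    ))
  }
  bad <- which(!is.na(pedigree$dam) & is.na(di))
  if (length(bad)) {
    stop_morphherit(sprintf(
      "dam label(s) not found in pedigree: %s",
      paste(unique(pedigree$dam[bad]), collapse = ", ")
    ))
  }
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE)) {
    stop_morphherit("pedigree is not topologically ordered: a parent follows its offspring.")
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

#' Read / write a pedigree CSV
#'
#' Headered CSV with columns `id`, `sire`, `dam`, `strain` and optionally
#' `family`, `sex`, `generation`; the string `"NA"` (or an empty field)
#' denotes an unknown parent.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a tibble; `write_pedigree()` invisibly
#'   returns `path`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop_morphherit(sprintf(
      "pedigree file must have columns %s.",
      paste(need, collapse = ", ")
    ))
  }
  tibble::as_tibble(df)
}

#' @rdname read_pedigree
#' @param pedigree Pedigree data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, na = "NA")
  invisible(path)
}
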