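#' Construct a sorted pedigree
#'
#' Builds a validated pedigree object from animal/sire/dam records. Animals
#' are re-ordered parents-first by a Kahn topological sort, with ties broken
#' by `birth_order` and then by identifier, so downstream matrix algebra is
#' deterministic. Parents that appear only in the sire or dam columns are
#' added as founder records with unknown breed.
#'
#' @param animal character vector of animal identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` or `""`
#'   denotes an unrecorded parent.
#' @param birth_order numeric vector ranking animals by age (smaller = older).
#'   Defaults to the input order.
#' @param breed optional character vector of breed-group labels
#'   (`"saanen"`, `"anto"`, `"unknown"`); only founder labels are used when
#'   deriving breed composition. Defaults to `"unknown"`.
#' @return A `data.frame` of class `goat_pedigree` with columns
#'   `animal`, `sire`, `dam`, `birth_order`, `breed`, sorted parents-first.
#' @examples
#' ped <- goat_pedigree(c("o", "s", "d"), c("s", NA, NA), c("d", NA, NA))
#' ped$animal  # parents precede offspring
#' @export
goat_pedigree <- function(animal, sire = NA, dam = NA, birth_order = NULL,
                          breed = NULL) {
  animal <- as.character(animal)
  n0 <- length(animal)
  sire <- .norm_id(rep_len(as.character(sire), n0))
  dam  <- .norm_id(rep_len(as.character(dam), n0))
  if (anyDuplicated(animal))
    stop("duplicate animal identifiers: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (is.null(birth_order)) birth_order <- seq_len(n0)
  birth_order <- rep_len(as.numeric(birth_order), n0)
  if (is.null(breed)) breed <- rep("unknown", n0)
  breed <- rep_len(tolower(as.character(breed)), n0)
  breed[is.na(breed) | breed == ""] <- "unknown"
  bad <- setdiff(unique(breed), breed_groups())
  if (length(bad))
    stop("unknown breed labels: ", paste(bad, collapse = ", "))

  # implicit parents become founders, older than any listed animal
  extra <- setdiff(c(sire, dam), c(animal, NA))
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    birth_order <- c(birth_order, rep(min(birth_order) - 1, length(extra)))
    breed <- c(breed, rep("unknown", length(extra)))
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire]); di <- unname(idx[dam])

  # Kahn topological sort; ties by (birth_order, animal id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ready <- idx[indeg == 0L]
  out <- integer(0)
  while (length(ready)) {
    ord <- order(birth_order[ready], animal[ready])
    ready <- ready[ord]
    i <- ready[1]; ready <- ready[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) < n)
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(idx, out)], collapse = ", "))

  ped <- data.frame(animal = animal[out], sire = sire[out], dam = dam[out],
                    birth_order = birth_order[out], breed = breed[out],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(ped) <- c("goat_pedigree", "data.frame")
  ped
}

.norm_id <- function(x) {
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

#' Breed-group labels
#'
#' The three breed groups of the multibreed model: Saanen, the ANTO aggregate
#' (Alpine, Nubian, Toggenburg, other breeds) and the unknown group.
#' @return Character vector of the group labels in canonical order.
#' @export
breed_groups <- function() c("saanen", "anto", "unknown")

#' @export
print.goat_pedigree <- function(x, ...) {
  cat("goat_pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  NextMethod()
}

.parent_idx <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$animal
  list(s = unname(idx[ped$sire]), d = unname(idx[ped$dam]))
}

#' Numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix `A` by the tabular
#' method, accounting fully for inbreeding: the diagonal is `1 + F_i` with
#' `F_i = a(sire, dam) / 2`.
#'
#' @param ped a [goat_pedigree()].
#' @return A dense symmetric matrix with animal identifiers as dimnames.
#' @examples
#' ped <- goat_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' relationship_matrix(ped)["o", "s"]  # 0.5
#' @seealso [relationship_inverse()], [partition_relationship()]
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "goat_pedigree"))
  pi_ <- .parent_idx(ped)
  si <- pi_$s; si[is.na(si)] <- 0L
  di <- pi_$d; di[is.na(di)] <- 0L
  A <- .tabular_A_cpp(as.integer(si), as.integer(di))
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients
#'
#' @param ped a [goat_pedigree()].
#' @return Named numeric vector `F_i = A_ii - 1`.
#' @export
inbreeding <- function(ped) {
  diag(relationship_matrix(ped)) - 1
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds `A^-1` directly by Henderson's rules with the inbreeding
#' adjustment: the Mendelian sampling variance of animal `i` is
#' `0.5 - (F_s + F_d)/4` when both parents are known, `0.75 - F_p/4` with
#' one known parent `p`, and 1 for a founder, with `F` the inbreeding
#' coefficients from the tabular relationship matrix.
#'
#' @param ped a [goat_pedigree()].
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with animal
#'   identifiers as dimnames.
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "goat_pedigree"))
  n <- nrow(ped)
  Fi <- diag(relationship_matrix(ped)) - 1  # inbreeding coefficients
  pi_ <- .parent_idx(ped)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- pi_$s[i]; d <- pi_$d[i]
    # Mendelian sampling variance: 1, 0.75 - F_p/4, or 0.5 - (F_s + F_d)/4
    m <- 1
    if (!is.na(s)) m <- m - 0.25 * (1 + Fi[s])
    if (!is.na(d)) m <- m - 0.25 * (1 + Fi[d])
    al <- 1 / m
    add(i, i, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -al / 2); add(p, i, -al / 2)
      }
    }
    ps <- c(s, d); ps <- ps[!is.na(ps)]
    for (p1 in ps) for (p2 in ps) add(p1, p2, al / 4)
  }
  keep <- seq_len(k)
  Ainv <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                               dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Partition a relationship matrix by genotyping status
#'
#' Splits `A` into the blocks used by the single-step model: `Agg`
#' (genotyped x genotyped), `Ang` (non-genotyped x genotyped), `Agn` and
#' `Ann`, all taken from one permutation of the animals.
#'
#' @param A relationship matrix with animal dimnames.
#' @param genotyped_ids character vector of genotyped animal identifiers;
#'   must be non-empty and a subset of the animals in `A`.
#' @return List with elements `Agg`, `Ang`, `Agn`, `Ann`, `genotyped`,
#'   `nongenotyped`.
#' @export
partition_relationship <- function(A, genotyped_ids) {
  ids <- rownames(A)
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) == 0)
    stop("at least one genotyped animal is required")
  if (!all(genotyped_ids %in% ids))
    stop("genotyped animals absent from the relationship matrix: ",
         paste(setdiff(genotyped_ids, ids), collapse = ", "))
  g <- ids[ids %in% genotyped_ids]
  ng <- setdiff(ids, g)
  list(Agg = A[g, g, drop = FALSE],
       Ang = A[ng, g, drop = FALSE],
       Agn = A[g, ng, drop = FALSE],
       Ann = A[ng, ng, drop = FALSE],
       genotyped = g, nongenotyped = ng)
}

#' Breed composition from pedigree proportions
#'
#' Each founder with a recorded breed label is assigned proportion 1 in that
#' group; founders without a label are fully "unknown". Every non-founder's
#' fractions are the average of its parents' fractions, an unrecorded parent
#' contributing fractions (0, 0, 1), i.e. all "unknown".
#'
#' @param ped a [goat_pedigree()].
#' @return Numeric matrix (animals x 3) with columns
#'   `saanen`, `anto`, `unknown`; rows sum to 1.
#' @examples
#' ped <- goat_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"),
#'                      breed = c("saanen", "anto", NA))
#' breed_composition(ped)["o", ]  # F1: 0.5 / 0.5 / 0
#' @export
breed_composition <- function(ped) {
  stopifnot(inherits(ped, "goat_pedigree"))
  n <- nrow(ped)
  pi_ <- .parent_idx(ped)
  comp <- matrix(0, n, 3, dimnames = list(ped$animal, breed_groups()))
  unknown_row <- c(0, 0, 1)
  for (i in seq_len(n)) {
    s <- pi_$s[i]; d <- pi_$d[i]
    if (is.na(s) && is.na(d)) {
      comp[i, ped$breed[i]] <- 1
    } else {
      fs <- if (is.na(s)) unknown_row else comp[s, ]
      fd <- if (is.na(d)) unknown_row else comp[d, ]
      comp[i, ] <- (fs + fd) / 2
    }
  }
  comp
}

#' General heterosis
#'
#' The expected proportion of heterozygous breed-group combinations,
#' `1 - sum_j d_j^2` over the breed-group fractions `d_j` of an animal.
#' A purebred has heterosis 0; an F1 between two groups has exactly 0.5.
#'
#' @param composition matrix from [breed_composition()].
#' @param animal optional identifiers; defaults to all rows.
#' @return Named numeric vector in `[0, 1 - 1/3]`.
#' @export
heterosis <- function(composition, animal = rownames(composition)) {
  m <- composition[animal, , drop = FALSE]
  1 - rowSums(m^2)
}
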