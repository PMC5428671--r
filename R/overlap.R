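## Pianka's symmetric niche overlap index, species mean overlaps, and the
## assemblage mean. Utilisation profiles are the row proportions of the
## community matrix, so overlap is invariant to rescaling any species' row.

#' Utilisation profiles of a community matrix
#'
#' Converts abundances to proportions of resource use per species:
#' p_ij = abundance_ij / (row total of species j). Species with zero total
#' abundance are excluded first (with a warning), since their profile is
#' undefined.
#'
#' @param m a [community_matrix()].
#' @param quiet suppress the exclusion warning.
#' @return A numeric matrix of the same shape whose rows each sum to 1.
#' @export
utilization <- function(m, quiet = FALSE) {
  m <- drop_empty_species(m, quiet = quiet)
  sweep(m$abundance, 1L, rowSums(m$abundance), "/")
}

#' Pianka's niche overlap index for a pair of profiles
#'
#' O_jk = sum_i p_ij p_ik / sqrt(sum_i p_ij^2 * sum_i p_ik^2). The index is
#' symmetric in j and k and bounded in \[0, 1\]: 0 when the two species use
#' disjoint sets of resource states, 1 when their utilisation profiles are
#' proportional.
#'
#' @param pj,pk non-negative numeric vectors of equal length (utilisation
#'   profiles; they need not be normalised, as the index is scale-invariant).
#' @return The overlap value.
#' @export
pianka <- function(pj, pk) {
  if (length(pj) != length(pk))
    .stopf("profiles differ in length (%d vs %d)", length(pj), length(pk))
  if (any(pj < 0) || any(pk < 0)) .stopf("profiles must be non-negative")
  nj <- sum(pj * pj); nk <- sum(pk * pk)
  if (nj == 0 || nk == 0) .stopf("all-zero utilisation profile")
  min(1, sum(pj * pk) / sqrt(nj * nk))
}

#' Pairwise niche overlap within an assemblage
#'
#' Computes the full symmetric matrix of Pianka overlaps, each species' mean
#' pairwise overlap with all other species (O_sp), and the assemblage mean
#' (the average over all unordered species pairs). Diagonal entries are set
#' to 1 but never enter O_sp or the assemblage mean.
#'
#' With `meta` and `category`, the assemblage is first restricted to the
#' species of that ecological category; since profiles are per-species row
#' proportions, subsetting does not change any pairwise value.
#'
#' @param m a [community_matrix()].
#' @param meta optional [species_metadata()] (required with `category`).
#' @param category optional `"stygobite"` or `"non_stygobite"`.
#' @param quiet suppress the zero-abundance exclusion warning.
#' @return An object of class `overlap_result`: list with `label`,
#'   `species_ids`, the symmetric matrix `O`, the vector `O_sp`,
#'   `mean_overall`, and `n_species`.
#' @examples
#' ab <- matrix(c(10, 0, 5, 5, 0, 10), nrow = 3, byrow = TRUE,
#'              dimnames = list(paste0("sp", 1:3), c("siteA", "siteB")))
#' niche_overlap(community_matrix(ab, "toy"))
#' @export
niche_overlap <- function(m, meta = NULL, category = NULL, quiet = FALSE) {
  stopifnot(inherits(m, "community_matrix"))
  if (!is.null(category)) {
    if (is.null(meta)) .stopf("category subsetting requires metadata")
    m <- subset_category(m, meta, category)
  }
  P <- utilization(m, quiet = quiet)
  if (nrow(P) < 2L) .stopf("need at least 2 species with positive abundance")
  O <- .pianka_matrix(P)
  S <- nrow(O)
  O_sp <- (rowSums(O) - 1) / (S - 1)
  structure(list(label = m$label,
                 species_ids = rownames(P),
                 O = O,
                 O_sp = O_sp,
                 mean_overall = mean(.upper_pairs(O)),
                 n_species = S),
            class = "overlap_result")
}

## cosine-similarity form of the pairwise Pianka matrix; rows of P must be
## nonzero. Values are clamped to [0, 1] against fp round-off.
.pianka_matrix <- function(P) {
  Q <- P / sqrt(rowSums(P * P))
  O <- tcrossprod(Q)
  O[O > 1] <- 1
  O[O < 0] <- 0
  diag(O) <- 1
  O
}

.pianka_mean <- function(P) {
  O <- tcrossprod(P / sqrt(rowSums(P * P)))
  mean(O[upper.tri(O)])
}

#' @export
print.overlap_result <- function(x, digits = 3, ...) {
  cat(sprintf("Pianka niche overlap, assemblage '%s' (%d species)\n",
              x$label, x$n_species))
  cat(sprintf("  mean pairwise overlap: %.*f\n", digits, x$mean_overall))
  cat(sprintf("  O_sp range: %.*f - %.*f\n", digits, min(x$O_sp),
              digits, max(x$O_sp)))
  invisible(x)
}
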