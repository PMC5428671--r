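## Stone-Roberts C-score: a descriptive measure of pairwise species
## segregation on presence/absence data. No null-model testing is attached:
## the matrix-wide average is used only to compare segregation across
## assemblages (higher C = less random, more segregated co-occurrence).

#' C-score for one species pair
#'
#' C_jk = (R_j - SS)(R_k - SS), where R_j and R_k are the numbers of samples
#' occupied by species j and k and SS is the number of samples occupied by
#' both. The score ranges from 0 (maximal aggregation: one species' samples
#' contain the other) to R_j * R_k (maximal segregation: no shared samples).
#'
#' @param pm a [to_presence()] matrix (or a `community_matrix`, thresholded
#'   at abundance > 0).
#' @param j,k species identifiers (or row indices).
#' @return The pairwise C-score.
#' @export
c_score_pair <- function(pm, j, k) {
  pm <- to_presence(pm)
  inc <- pm$incidence
  for (id in list(j, k))
    if (is.character(id) && !id %in% rownames(inc))
      .stopf("unknown species id: %s", id)
  if (identical(j, k)) .stopf("need two distinct species")
  rj <- inc[j, ]; rk <- inc[k, ]
  ss <- sum(rj * rk)
  (sum(rj) - ss) * (sum(rk) - ss)
}

#' Matrix-wide C-score
#'
#' Computes all pairwise C-scores and their mean over the unordered species
#' pairs. Because the pairwise score reflects both positively and negatively
#' associated pairs, the matrix-wide average summarises how non-random the
#' assemblage's co-occurrence structure is.
#'
#' A species present in no sample contributes 0 with every partner
#' (R_j = 0 implies SS = 0); by default such species are excluded, mirroring
#' the overlap module's filtering, but they can be kept with
#' `drop_empty = FALSE`.
#'
#' @param x a `community_matrix` or `presence_matrix`.
#' @param meta,category optional metadata and ecological category restricting
#'   the computation to one species group.
#' @param drop_empty exclude species present in no sample.
#' @return An object of class `cscore_result`: list with `label`,
#'   `species_ids`, the symmetric matrix `pairwise_c` (diagonal `NA`), and
#'   `mean_c`.
#' @export
c_score <- function(x, meta = NULL, category = NULL, drop_empty = TRUE) {
  if (inherits(x, "community_matrix") && !is.null(category)) {
    if (is.null(meta)) .stopf("category subsetting requires metadata")
    x <- subset_category(x, meta, category)
  }
  pm <- to_presence(x)
  inc <- pm$incidence
  if (drop_empty) inc <- inc[rowSums(inc) > 0, , drop = FALSE]
  if (nrow(inc) < 2L) .stopf("need at least 2 species")
  R <- rowSums(inc)
  SS <- tcrossprod(inc)
  C <- (R - SS) * t(R - t(SS))   # (R_j - SS_jk)(R_k - SS_jk)
  diag(C) <- NA_real_
  structure(list(label = pm$label,
                 species_ids = rownames(inc),
                 pairwise_c = C,
                 mean_c = mean(.upper_pairs(C))),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, digits = 3, ...) {
  cat(sprintf("C-score, assemblage '%s' (%d species): mean C = %.*f\n",
              x$label, length(x$species_ids), digits, x$mean_c))
  invisible(x)
}
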