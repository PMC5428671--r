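## RA1-RA4 randomisation algorithms for resource utilisation matrices and the
## Monte Carlo significance test of mean niche overlap against simulated null
## assemblages.

RA_ALGORITHMS <- c("RA1", "RA2", "RA3", "RA4")

## per-row randomisation on the utilisation (row-proportion) scale.
## RA1: every entry replaced by an independent uniform(0,1) draw -- niche
##      breadth relaxed, zero states not retained.
## RA2: zero entries retained; nonzero entries replaced by uniform(0,1)
##      draws -- breadth relaxed, guild (zero) structure conserved.
## RA3: each row's values permuted across all resource states -- breadth
##      retained, zero states reshuffled.
## RA4: each row's nonzero values permuted among the nonzero positions --
##      breadth retained, zero states fixed.
## RA1/RA2 rows are re-normalised to sum 1 (inconsequential for Pianka's
## scale-invariant index, applied for tidiness); uniform draws are on the
## open interval so a nonzero entry can never become zero.
.randomize_rows <- function(P, algorithm) {
  n <- ncol(P)
  switch(algorithm,
    RA1 = {
      R <- matrix(runif(length(P)), nrow = nrow(P), dimnames = dimnames(P))
      R / rowSums(R)
    },
    RA2 = {
      R <- P
      nz <- R > 0
      R[nz] <- runif(sum(nz))
      R / rowSums(R)
    },
    RA3 = {
      R <- t(apply(P, 1L, function(row) unname(row)[sample.int(n)]))
      dimnames(R) <- dimnames(P)
      R
    },
    RA4 = {
      R <- t(apply(P, 1L, function(row) {
        idx <- which(row > 0)
        if (length(idx) > 1L) row[idx] <- row[idx][sample.int(length(idx))]
        unname(row)
      }))
      dimnames(R) <- dimnames(P)
      R
    },
    .stopf("unknown algorithm '%s' (use one of %s)", algorithm,
           paste(RA_ALGORITHMS, collapse = ", "))
  )
}

#' Randomise a community matrix under a null-model algorithm
#'
#' Generates one simulated null assemblage from an observed community matrix.
#' The four classical algorithms differ in whether each species' niche
#' breadth is retained (observed utilisation values reshuffled: RA3, RA4) or
#' relaxed (values replaced by uniform random draws: RA1, RA2), and in
#' whether the zero states of the matrix are retained (RA2, RA4) or not
#' (RA1, RA3). RA3 -- which keeps each species' degree of specialisation but
#' randomises which resource states it uses -- is the standard choice for
#' resource-overlap null models; RA2 conserves the guild structure carried by
#' the zeros instead.
#'
#' Randomisation operates on the utilisation (row-proportion) scale, so the
#' result is a community matrix of proportions.
#'
#' @param m a [community_matrix()]; species with zero total abundance are
#'   excluded first.
#' @param algorithm one of `"RA1"`, `"RA2"`, `"RA3"`, `"RA4"`.
#' @return A `community_matrix` of utilisation proportions with the same
#'   retained species and resource states.
#' @export
randomize <- function(m, algorithm = "RA3") {
  stopifnot(inherits(m, "community_matrix"))
  if (length(algorithm) != 1L || !algorithm %in% RA_ALGORITHMS)
    .stopf("unknown algorithm '%s' (use one of %s)", algorithm[1L],
           paste(RA_ALGORITHMS, collapse = ", "))
  P <- utilization(m, quiet = TRUE)
  community_matrix(.randomize_rows(P, algorithm),
                   label = paste(m$label, algorithm, sep = ":"))
}

#' Null-model test of mean niche overlap
#'
#' Compares the observed assemblage mean Pianka overlap with the distribution
#' of mean overlaps in simulated null assemblages generated by one of the
#' RA1-RA4 algorithms. The reported tail probability is
#' `p_ge = P(null mean >= observed mean)`, the raw proportion of null
#' assemblages whose mean overlap reaches the observed one: small values
#' indicate observed overlap higher than expected by chance (aggregated use
#' of resource states), values near 1 indicate overlap below expectation
#' (segregation).
#'
#' @param m a [community_matrix()].
#' @param algorithm one of `"RA1"`, `"RA2"`, `"RA3"`, `"RA4"`.
#' @param iterations number of simulated null assemblages.
#' @param seed optional integer seed; with a fixed seed the result is
#'   bit-identical across runs.
#' @param meta,category optional metadata and ecological category restricting
#'   the test to one species group; the null means are computed on the same
#'   subset as the observed mean.
#' @param pseudo_count if `TRUE`, report `(count + 1) / (iterations + 1)`
#'   instead of the raw proportion.
#' @param quiet suppress the zero-abundance exclusion warning.
#' @return An object of class `null_model_result`: list with `label`,
#'   `algorithm`, `iterations`, `seed`, `observed_mean`, `expected_mean`
#'   (mean of the null means), `null_variance` (population variance of the
#'   null means, divisor = iterations, an ensemble descriptor), `p_ge`, and
#'   the vector `null_means`.
#' @examples
#' cfg <- synthetic_config(n_species = 10, seed = 7)
#' com <- generate_community(cfg)
#' null_model_test(com$matrix, "RA3", iterations = 100, seed = 7)
#' @export
null_model_test <- function(m, algorithm = "RA3", iterations = 1000,
                            seed = NULL, meta = NULL, category = NULL,
                            pseudo_count = FALSE, quiet = FALSE) {
  stopifnot(inherits(m, "community_matrix"))
  if (length(algorithm) != 1L || !algorithm %in% RA_ALGORITHMS)
    .stopf("unknown algorithm '%s' (use one of %s)", algorithm[1L],
           paste(RA_ALGORITHMS, collapse = ", "))
  if (iterations < 1L) .stopf("iterations must be >= 1")
  if (!is.null(category)) {
    if (is.null(meta)) .stopf("category subsetting requires metadata")
    m <- subset_category(m, meta, category)
  }
  m <- drop_empty_species(m, quiet = quiet)
  P <- sweep(m$abundance, 1L, rowSums(m$abundance), "/")
  observed <- .pianka_mean(P)
  if (!is.null(seed)) set.seed(seed)
  null_means <- vapply(seq_len(iterations), function(i)
    .pianka_mean(.randomize_rows(P, algorithm)), numeric(1L))
  expected <- mean(null_means)
  count <- sum(null_means >= observed)
  p_ge <- if (pseudo_count) (count + 1) / (iterations + 1) else count / iterations
  structure(list(label = m$label,
                 algorithm = algorithm,
                 iterations = as.integer(iterations),
                 seed = seed %||% NA_integer_,
                 observed_mean = observed,
                 expected_mean = expected,
                 null_variance = mean((null_means - expected)^2),
                 p_ge = p_ge,
                 null_means = null_means),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, digits = 3, ...) {
  cat(sprintf("Null-model test (%s, %d iterations), assemblage '%s'\n",
              x$algorithm, x$iterations, x$label))
  cat(sprintf("  observed mean overlap:  %.*f\n", digits, x$observed_mean))
  cat(sprintf("  expected overlap +- variance: %.*f +- %.*f\n",
              digits, x$expected_mean, digits, x$null_variance))
  cat(sprintf("  P(observed >= expected): %.*f\n", digits, x$p_ge))
  invisible(x)
}
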