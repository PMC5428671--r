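# Brute-force oracles and tiny fixture builders, independent of the package's
# vectorised implementations.

toy_matrix <- function(values, species = NULL, sites = NULL, label = "toy") {
  ab <- as.matrix(values)
  rownames(ab) <- species %||% paste0("sp", seq_len(nrow(ab)))
  colnames(ab) <- sites %||% paste0("site", seq_len(ncol(ab)))
  community_matrix(ab, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pianka's index evaluated literally from the printed formula, one pair at a
# time, on row proportions.
brute_pianka_matrix <- function(ab) {
  P <- ab / rowSums(ab)
  S <- nrow(P)
  O <- diag(1, S)
  for (j in seq_len(S)) for (k in seq_len(S)) if (j != k) {
    num <- 0; dj <- 0; dk <- 0
    for (i in seq_len(ncol(P))) {
      num <- num + P[j, i] * P[k, i]
      dj <- dj + P[j, i]^2
      dk <- dk + P[k, i]^2
    }
    O[j, k] <- num / sqrt(dj * dk)
  }
  dimnames(O) <- list(rownames(ab), rownames(ab))
  O
}

# Checkerboard form of the pairwise C-score: explicit nested-loop count of
# occupied/unoccupied sample combinations.
brute_cscore_pair <- function(inc, j, k) {
  rj <- 0; rk <- 0; ss <- 0
  for (s in seq_len(ncol(inc))) {
    if (inc[j, s] > 0) rj <- rj + 1
    if (inc[k, s] > 0) rk <- rk + 1
    if (inc[j, s] > 0 && inc[k, s] > 0) ss <- ss + 1
  }
  (rj - ss) * (rk - ss)
}

# Type III mixed-design (split-plot) decomposition by brute-force projection:
# between stratum on subject means, within stratum by dropping each effect's
# sum-coded columns from the full design matrix (subject dummies + year +
# year:group) and differencing residual sums of squares.
oracle_rm_anova <- function(Y, g) {
  n <- nrow(Y); t <- ncol(Y)
  g <- factor(g)
  m <- rowMeans(Y)
  fitb <- lm(m ~ g, contrasts = list(g = "contr.sum"))
  ss_group <- t * anova(fitb)[1, "Sum Sq"]
  ss_err_b <- t * sum(residuals(fitb)^2)
  long <- data.frame(y = as.vector(Y),
                     subj = factor(rep(seq_len(n), t)),
                     year = factor(rep(seq_len(t), each = n)),
                     g = rep(g, t))
  X <- model.matrix(~ subj + year + year:g, long,
                    contrasts.arg = list(subj = "contr.sum",
                                         year = "contr.sum",
                                         g = "contr.sum"))
  asn <- attr(X, "assign")
  rss <- function(M) sum(lm.fit(M, long$y)$residuals^2)
  rf <- rss(X)
  list(ss_group = ss_group, ss_err_between = ss_err_b,
       ss_year = rss(X[, asn != 2, drop = FALSE]) - rf,
       ss_interaction = rss(X[, asn != 3, drop = FALSE]) - rf,
       ss_err_within = rf)
}

random_community <- function(n_species, n_sites, max_count = 9,
                             ensure_positive_rows = TRUE) {
  repeat {
    ab <- matrix(sample(0:max_count, n_species * n_sites, replace = TRUE),
                 n_species, n_sites)
    if (!ensure_positive_rows || all(rowSums(ab) > 0)) break
  }
  toy_matrix(ab, label = "random")
}
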