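## Between-year comparison of pairwise overlap (O), species mean overlap
## (O_sp) and pairwise C-scores: pair-type classification, mixed-design
## repeated-measures ANOVA with Type III sums of squares, Bonferroni post
## hocs, and paired t-tests.

#' Classify a species pair by ecological category
#'
#' @param a,b species identifiers.
#' @param meta a [species_metadata()] covering both species.
#' @return `"ss"` (both stygobites), `"nn"` (neither), or `"sn"` (mixed;
#'   order-independent).
#' @export
classify_pair <- function(a, b, meta) {
  stopifnot(inherits(meta, "species_metadata"))
  missing <- setdiff(c(a, b), names(meta))
  if (length(missing))
    .stopf("species missing from metadata: %s", paste(missing, collapse = ", "))
  n_styg <- sum(meta[c(a, b)] == "stygobite")
  c("nn", "sn", "ss")[n_styg + 1L]
}

.value_matrix <- function(res) {
  if (inherits(res, "overlap_result")) return(res$O)
  if (inherits(res, "cscore_result")) return(res$pairwise_c)
  .stopf("expected overlap_result or cscore_result objects")
}

#' Build the cross-year pair table
#'
#' Collects, for every species pair whose members are retained (positive
#' abundance) in every year, the pairwise value (Pianka O, or pairwise
#' C-score) in each year, together with the ecological pair type. Pairs
#' involving a species absent from any year are excluded -- the data-driven
#' analogue of dropping species not seen in all years.
#'
#' @param results named list (one element per year) of [niche_overlap()]
#'   results, or of [c_score()] results.
#' @param meta a [species_metadata()].
#' @return A data frame of class `pair_table` with columns `subject`,
#'   `species_a`, `species_b`, `pair_type` and one numeric column per year;
#'   attribute `"years"` holds the year column names. Zero rows (with a
#'   warning) if fewer than two species are shared.
#' @export
build_pair_table <- function(results, meta) {
  if (length(results) < 2L || is.null(names(results)))
    .stopf("need a named list of >= 2 yearly results")
  years <- names(results)
  common <- Reduce(intersect, lapply(results, `[[`, "species_ids"))
  if (length(common) < 2L) {
    warning("fewer than 2 species shared across all years; empty pair table",
            call. = FALSE)
    tab <- data.frame(subject = character(), species_a = character(),
                      species_b = character(), pair_type = character())
    for (y in years) tab[[y]] <- numeric()
    return(structure(tab, years = years, class = c("pair_table", "data.frame")))
  }
  common <- sort(common)
  pairs <- utils::combn(common, 2L)
  tab <- data.frame(
    subject = paste(pairs[1L, ], pairs[2L, ], sep = ":"),
    species_a = pairs[1L, ],
    species_b = pairs[2L, ],
    pair_type = mapply(classify_pair, pairs[1L, ], pairs[2L, ],
                       MoreArgs = list(meta = meta)),
    stringsAsFactors = FALSE
  )
  for (y in years) {
    V <- .value_matrix(results[[y]])
    tab[[y]] <- V[cbind(tab$species_a, tab$species_b)]
  }
  structure(tab, years = years, class = c("pair_table", "data.frame"))
}

#' Build the cross-year species table
#'
#' One row per species retained in every year, with its specialisation
#' (stygobite / non-stygobite) and its mean pairwise overlap O_sp per year.
#' O_sp values come from each year's full assemblage result, i.e. they
#' average over all of that year's pairwise values -- including partners that
#' the all-years filter later drops from the pair table.
#'
#' @param results named list of [niche_overlap()] results (one per year).
#' @param meta a [species_metadata()].
#' @return A data frame of class `pair_table` with columns `subject`,
#'   `specialisation` and one O_sp column per year.
#' @export
build_species_table <- function(results, meta) {
  if (length(results) < 2L || is.null(names(results)))
    .stopf("need a named list of >= 2 yearly results")
  stopifnot(all(vapply(results, inherits, logical(1L), "overlap_result")))
  years <- names(results)
  common <- sort(Reduce(intersect, lapply(results, `[[`, "species_ids")))
  missing <- setdiff(common, names(meta))
  if (length(missing))
    .stopf("species missing from metadata: %s", paste(missing, collapse = ", "))
  tab <- data.frame(subject = common,
                    specialisation = unname(meta[common]),
                    stringsAsFactors = FALSE)
  for (y in years) tab[[y]] <- results[[y]]$O_sp[common]
  structure(tab, years = years, class = c("pair_table", "data.frame"))
}

#' Mixed-design repeated-measures ANOVA with Type III sums of squares
#'
#' Univariate split-plot decomposition for a design with one between-subjects
#' factor (pair type, or species specialisation) and one within-subjects
#' factor (year). Subjects are species pairs (for O) or species (for O_sp);
#' every subject must be measured in every year, while group sizes may be
#' unequal. Effects are adjusted for each other via a sum-to-zero-coded
#' cell-means model (Type III), so with unequal groups the year effect is the
#' test of the unweighted marginal means.
#'
#' Greenhouse-Geisser and Huynh-Feldt sphericity corrections are computed and
#' attached (attributes `"sphericity"` and `"corrections"`), but the
#' uncorrected P values are the headline figures.
#'
#' @param table a [build_pair_table()] or [build_species_table()] data frame.
#' @param between name of the between-subjects factor column
#'   (`"pair_type"` or `"specialisation"`).
#' @return A data frame of class `rm_anova` with one row per effect --
#'   between factor, its subject-within-group error, year, year x factor
#'   interaction, and the within error -- and columns `effect`, `SS`, `df`,
#'   `MS`, `F`, `P`.
#' @export
rm_anova <- function(table, between) {
  years <- attr(table, "years")
  if (is.null(years)) .stopf("table must carry a 'years' attribute")
  if (!between %in% names(table)) .stopf("no column '%s' in table", between)
  Y <- as.matrix(table[, years, drop = FALSE])
  if (anyNA(Y)) .stopf("subjects with missing year values are not supported")
  if (nrow(Y) < 3L) .stopf("need at least 3 subjects")
  g <- factor(table[[between]])
  if (any(tabulate(g) < 2L))
    .stopf("every level of '%s' needs at least 2 subjects", between)
  dat <- data.frame(.group = g)
  mlm <- lm(Y ~ .group, data = dat,
            contrasts = list(.group = "contr.sum"))
  idata <- data.frame(time = factor(years, levels = years))
  av <- car::Anova(mlm, idata = idata, idesign = ~time, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1 and is clamped; that is
  # expected behaviour, not a problem with the fit
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  u <- s$univariate.tests
  grab <- function(row) u[row, c("Sum Sq", "num Df", "Error SS", "den Df",
                                 "F value", "Pr(>F)")]
  b <- grab(".group"); w <- grab("time"); i <- grab(".group:time")
  out <- data.frame(
    effect = c(between, "Error (between)", "year",
               paste0("year x ", between), "Error (within)"),
    SS = c(b[1], b[3], w[1], i[1], w[3]),
    df = c(b[2], b[4], w[2], i[2], w[4]),
    F = c(b[5], NA, w[5], i[5], NA),
    P = c(b[6], NA, w[6], i[6], NA),
    stringsAsFactors = FALSE
  )
  out$MS <- out$SS / out$df
  out <- out[, c("effect", "SS", "df", "MS", "F", "P")]
  structure(out,
            sphericity = s$sphericity.tests,
            corrections = s$pval.adjustments,
            class = c("rm_anova", "data.frame"))
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat("Mixed-design repeated-measures ANOVA (Type III SS)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  corr <- attr(x, "corrections")
  if (!is.null(corr) && length(corr))
    cat(sprintf("Greenhouse-Geisser epsilon %.3f (corrected P attached)\n",
                corr[1, "GG eps"]))
  invisible(x)
}

## t statistic that degrades gracefully when the variance is zero
.safe_t <- function(diffs) {
  n <- length(diffs)
  s <- sd(diffs)
  if (s == 0) {
    if (mean(diffs) == 0)
      return(list(t = 0, df = n - 1L, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(diffs)) * Inf, df = n - 1L, p = 0,
                degenerate = TRUE))
  }
  tt <- mean(diffs) / (s / sqrt(n))
  list(t = tt, df = n - 1L, p = 2 * pt(-abs(tt), n - 1L), degenerate = FALSE)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' All-pairs comparisons between the levels of the within-subjects factor
#' (years; paired t-tests on each subject's values) or the between-subjects
#' factor (groups; two-sample t-tests on subject means across years). Raw
#' two-sided P values are multiplied by the number of comparisons in the
#' family and capped at 1.
#'
#' @param table a [build_pair_table()] / [build_species_table()] data frame.
#' @param factor `"year"` or `"group"`.
#' @param between name of the grouping column (used when `factor = "group"`).
#' @return Data frame with one row per level pair: `level_a`, `level_b`,
#'   `mean_diff`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_pairwise <- function(table, factor = c("year", "group"),
                                between = "pair_type") {
  factor <- match.arg(factor)
  years <- attr(table, "years")
  if (factor == "year") {
    levels_ <- years
    cmp <- function(a, b) .safe_t(table[[a]] - table[[b]])
  } else {
    if (!between %in% names(table)) .stopf("no column '%s' in table", between)
    g <- factor(table[[between]])
    levels_ <- levels(g)
    means <- rowMeans(as.matrix(table[, years, drop = FALSE]))
    cmp <- function(a, b) {
      x <- means[g == a]; y <- means[g == b]
      tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                     error = function(e) NULL)
      if (is.null(tt))
        return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                    degenerate = TRUE))
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, degenerate = FALSE)
    }
  }
  if (length(levels_) < 2L) .stopf("need at least 2 levels to compare")
  combos <- utils::combn(levels_, 2L)
  n_comp <- ncol(combos)
  rows <- lapply(seq_len(n_comp), function(i) {
    a <- combos[1L, i]; b <- combos[2L, i]
    r <- cmp(a, b)
    md <- if (factor == "year") mean(table[[a]] - table[[b]])
          else mean(rowMeans(as.matrix(table[table[[between]] == a, years,
                                             drop = FALSE]))) -
               mean(rowMeans(as.matrix(table[table[[between]] == b, years,
                                             drop = FALSE])))
    data.frame(level_a = a, level_b = b, mean_diff = md, t = r$t, df = r$df,
               p_raw = r$p, p_adj = min(1, r$p * n_comp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-test between two years for one pair type
#'
#' Classical paired t statistic on the per-subject differences between two
#' years, restricted to one pair type (or all subjects when `pair_type` is
#' `NULL`). A zero-variance difference vector is reported as a degenerate
#' case (t = 0, P = 1 when all differences are zero) rather than an error.
#'
#' @param table a [build_pair_table()] data frame.
#' @param year_a,year_b year column names.
#' @param pair_type optional level of `between` to restrict to.
#' @param between grouping column name.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t <- function(table, year_a, year_b, pair_type = NULL,
                     between = "pair_type") {
  years <- attr(table, "years")
  if (!all(c(year_a, year_b) %in% years))
    .stopf("years must be among: %s", paste(years, collapse = ", "))
  if (!is.null(pair_type)) table <- table[table[[between]] == pair_type, ]
  if (nrow(table) < 2L) .stopf("need >= 2 subjects with both years")
  d <- table[[year_b]] - table[[year_a]]
  r <- .safe_t(d)
  c(r[c("t", "df", "p")], list(mean_diff = mean(d), n = length(d),
                               degenerate = r$degenerate))
}

#' Full multi-year niche-overlap report
#'
#' Orchestrates the whole analysis for a set of yearly community matrices:
#' per-year Pianka overlap (whole assemblage and per ecological category),
#' null-model tests under the requested algorithms, C-scores, the cross-year
#' pair and species tables, both repeated-measures ANOVAs (pairwise O by pair
#' type; O_sp by specialisation) plus a pairwise C-score ANOVA, Bonferroni
#' post hocs, and paired t-tests per pair type for every year pair.
#'
#' Per-task seeds for the null-model ensembles are derived deterministically
#' from `seed`, so a fixed seed makes the whole report reproducible
#' bit-exactly.
#'
#' @param matrices named list of [community_matrix()] objects, one per year.
#' @param meta a [species_metadata()].
#' @param iterations null-model iterations per test.
#' @param seed integer seed.
#' @param algorithms null-model algorithms to run.
#' @param categories ecological categories analysed separately (skipped with
#'   a warning when a year has fewer than 2 species of a category).
#' @return A list of class `year_report` with elements `overlap`, `null`,
#'   `cscore`, `pair_table`, `species_table`, `cscore_table`, `anova_O`,
#'   `anova_Osp`, `anova_C`, `bonferroni`, `paired_t`.
#' @export
year_report <- function(matrices, meta, iterations = 1000, seed = 1,
                        algorithms = c("RA2", "RA3"),
                        categories = c("stygobite", "non_stygobite")) {
  if (length(matrices) < 2L || is.null(names(matrices)))
    .stopf("need a named list of >= 2 yearly matrices")
  years <- names(matrices)
  subsets <- c(list(all = NULL), setNames(as.list(categories), categories))

  overlap <- lapply(years, function(y) {
    lapply(subsets, function(cat)
      tryCatch(niche_overlap(matrices[[y]], meta = meta, category = cat,
                             quiet = TRUE),
               error = function(e) {
                 warning(sprintf("overlap (%s, %s) skipped: %s", y,
                                 cat %||% "all", conditionMessage(e)),
                         call. = FALSE)
                 NULL
               }))
  })
  names(overlap) <- years

  task <- 0L
  null <- lapply(years, function(y) {
    out <- list()
    for (alg in algorithms)
      for (nm in names(subsets)) {
        task <<- task + 1L
        out[[paste(alg, nm, sep = ".")]] <- tryCatch(
          null_model_test(matrices[[y]], algorithm = alg,
                          iterations = iterations, seed = seed + task,
                          meta = meta, category = subsets[[nm]],
                          quiet = TRUE),
          error = function(e) NULL)
      }
    out
  })
  names(null) <- years

  cscore <- lapply(years, function(y) {
    lapply(subsets, function(cat)
      tryCatch(c_score(matrices[[y]], meta = meta, category = cat),
               error = function(e) NULL))
  })
  names(cscore) <- years

  overlap_all <- lapply(overlap, `[[`, "all")
  pair_table <- build_pair_table(overlap_all, meta)
  species_table <- build_species_table(overlap_all, meta)
  cscore_table <- build_pair_table(lapply(cscore, `[[`, "all"), meta)

  anova_O <- tryCatch(rm_anova(pair_table, between = "pair_type"),
                      error = function(e) NULL)
  anova_Osp <- tryCatch(rm_anova(species_table, between = "specialisation"),
                        error = function(e) NULL)
  anova_C <- tryCatch(rm_anova(cscore_table, between = "pair_type"),
                      error = function(e) NULL)

  bonf <- list(
    O_years = bonferroni_pairwise(pair_table, "year"),
    O_types = bonferroni_pairwise(pair_table, "group", between = "pair_type"),
    Osp_years = bonferroni_pairwise(species_table, "year"),
    Osp_specialisation = bonferroni_pairwise(species_table, "group",
                                             between = "specialisation"))

  year_pairs <- utils::combn(years, 2L)
  ptests <- list()
  for (tp in sort(unique(pair_table$pair_type)))
    for (i in seq_len(ncol(year_pairs))) {
      ya <- year_pairs[1L, i]; yb <- year_pairs[2L, i]
      ptests[[paste(tp, ya, yb, sep = ".")]] <- tryCatch(
        paired_t(pair_table, ya, yb, pair_type = tp),
        error = function(e) NULL)
    }

  structure(list(overlap = overlap, null = null, cscore = cscore,
                 pair_table = pair_table, species_table = species_table,
                 cscore_table = cscore_table, anova_O = anova_O,
                 anova_Osp = anova_Osp, anova_C = anova_C,
                 bonferroni = bonf, paired_t = ptests,
                 years = years, iterations = iterations, seed = seed),
            class = "year_report")
}

#' @export
print.year_report <- function(x, digits = 3, ...) {
  cat(sprintf("Niche-overlap report: years %s (%d null iterations, seed %d)\n",
              paste(x$years, collapse = ", "), x$iterations, x$seed))
  for (y in x$years) {
    ov <- x$overlap[[y]]$all
    cs <- x$cscore[[y]]$all
    cat(sprintf("  %s: mean O = %s; mean C = %s\n", y,
                if (is.null(ov)) "NA" else formatC(ov$mean_overall, digits = digits, format = "f"),
                if (is.null(cs)) "NA" else formatC(cs$mean_c, digits = digits, format = "f")))
    for (nm in names(x$null[[y]])) {
      nt <- x$null[[y]][[nm]]
      if (!is.null(nt))
        cat(sprintf("    %-18s obs %.3f, exp %.3f +- %.3f, P(obs>=exp) %.3f\n",
                    nm, nt$observed_mean, nt$expected_mean, nt$null_variance,
                    nt$p_ge))
    }
  }
  cat(sprintf("  pair table: %d pairs x %d years\n", nrow(x$pair_table),
              length(x$years)))
  invisible(x)
}
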