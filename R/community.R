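## Species x resource-state community matrices, species metadata, and the
## presence/absence view used by the co-occurrence statistics.

#' Construct a community matrix
#'
#' A community matrix holds the abundance of each species (rows) across a set
#' of resource states (columns) -- here, discrete spatial sampling units such
#' as spring outlets. Counts are used as a proxy for the amount of resource a
#' species uses at each state, so any non-negative values (including
#' normalised or simulated ones) are accepted.
#'
#' @param abundance numeric matrix (or data frame) of non-negative, finite
#'   values with species as row names and resource states as column names.
#' @param label character scalar identifying the assemblage, typically a year.
#' @return An object of class `community_matrix`: a list with elements
#'   `label` and `abundance`. Species whose row sums are zero are kept (they
#'   are flagged and excluded later by the overlap and co-occurrence
#'   computations, where they are undefined).
#' @seealso [read_community_matrix()], [to_presence()], [drop_empty_species()]
#' @export
community_matrix <- function(abundance, label = "community") {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance))
    .stopf("abundance must be numeric")
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    .stopf("abundance must have species row names and resource column names")
  if (anyDuplicated(rownames(abundance)))
    .stopf("duplicate species identifier: %s",
           paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
                 collapse = ", "))
  if (anyDuplicated(colnames(abundance)))
    .stopf("duplicate resource identifier: %s",
           paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
                 collapse = ", "))
  if (any(!is.finite(abundance)))
    .stopf("abundance values must be finite")
  if (any(abundance < 0))
    .stopf("negative abundance")
  if (nrow(abundance) < 2L || ncol(abundance) < 2L)
    .stopf("need at least 2 species and 2 resource states (got %d x %d)",
           nrow(abundance), ncol(abundance))
  structure(list(label = as.character(label)[1L], abundance = abundance),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix '%s': %d species x %d resource states\n",
              x$label, nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  total abundance %g; %d species with zero total\n",
              sum(x$abundance), sum(rowSums(x$abundance) == 0)))
  invisible(x)
}

#' @rdname community_matrix
#' @param m a `community_matrix`.
#' @export
species_ids <- function(m) rownames(m$abundance)

#' @rdname community_matrix
#' @export
resource_ids <- function(m) colnames(m$abundance)

#' Read a community matrix from CSV
#'
#' Expects a comma-separated file with a header row of resource-state
#' identifiers, species identifiers in the first column, and numeric
#' abundances elsewhere ("." decimal, UTF-8). The first header cell is
#' ignored. Species whose abundance sums to zero are reported via a message
#' but retained; downstream computations exclude them.
#'
#' When each column encodes a site crossed with a temporal replicate (for
#' example `S1_jan`, `S1_mar`, ...), `pool_sep` collapses replicates by
#' summing all columns that share the prefix before the separator, so the
#' sites become the resource states. Leave `pool_sep = NULL` to keep the
#' columns as read (e.g. to treat site x period combinations as distinct
#' states for sensitivity analysis).
#'
#' @param path path to a CSV file.
#' @param label assemblage label; defaults to the file name without extension.
#' @param pool_sep optional separator used to pool replicate columns by site.
#' @return A validated [community_matrix()].
#' @export
read_community_matrix <- function(path, label = NULL, pool_sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 3L || nrow(df) < 2L)
    .stopf("community CSV needs >= 2 species rows and >= 2 resource columns")
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  numeric_ok <- vapply(vals, is.numeric, logical(1L))
  if (!all(numeric_ok))
    .stopf("non-numeric abundance cell(s) in column(s): %s",
           paste(names(vals)[!numeric_ok], collapse = ", "))
  ab <- as.matrix(vals)
  rownames(ab) <- ids
  m <- community_matrix(ab, label = label %||% sub("\\.[^.]*$", "", basename(path)))
  if (!is.null(pool_sep)) m <- pool_replicates(m, sep = pool_sep)
  empty <- rownames(m$abundance)[rowSums(m$abundance) == 0]
  if (length(empty))
    message("species with zero total abundance (excluded from overlap/C-score): ",
            paste(empty, collapse = ", "))
  m
}

#' Write a community matrix to CSV
#'
#' Inverse of [read_community_matrix()]: integer abundances round-trip
#' exactly.
#'
#' @param m a `community_matrix`.
#' @param path output path.
#' @export
write_community_matrix <- function(m, path) {
  stopifnot(inherits(m, "community_matrix"))
  df <- data.frame(species = rownames(m$abundance), m$abundance,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool replicate columns into sites
#'
#' Sums groups of columns (e.g. bimonthly replicates of the same spring
#' outlet) so that each site becomes a single resource state. Groups are
#' either given explicitly or derived from the column names by splitting at
#' `sep` and keeping the prefix.
#'
#' @param m a `community_matrix`.
#' @param groups optional character vector, one entry per column, naming the
#'   site each column belongs to.
#' @param sep separator used to derive `groups` from column names when
#'   `groups` is `NULL`.
#' @return A `community_matrix` with one column per site, in order of first
#'   appearance.
#' @export
pool_replicates <- function(m, groups = NULL, sep = "_") {
  stopifnot(inherits(m, "community_matrix"))
  cols <- colnames(m$abundance)
  if (is.null(groups))
    groups <- sub(paste0(sep, ".*$"), "", cols, fixed = FALSE)
  if (length(groups) != length(cols))
    .stopf("groups must have one entry per column")
  sites <- unique(groups)
  pooled <- vapply(sites, function(s)
    rowSums(m$abundance[, groups == s, drop = FALSE]),
    numeric(nrow(m$abundance)))
  community_matrix(pooled, label = m$label)
}

#' Subset a community matrix
#'
#' @param m a `community_matrix`.
#' @param species character vector of species identifiers to keep.
#' @return A `community_matrix` restricted to `species` (order preserved as
#'   given).
#' @export
subset_community <- function(m, species) {
  stopifnot(inherits(m, "community_matrix"))
  missing <- setdiff(species, species_ids(m))
  if (length(missing))
    .stopf("unknown species id: %s", paste(missing, collapse = ", "))
  if (length(species) < 2L)
    .stopf("need at least 2 species after subsetting")
  community_matrix(m$abundance[species, , drop = FALSE], label = m$label)
}

#' Drop species with zero total abundance
#'
#' Overlap and co-occurrence statistics are undefined for a species never
#' recorded in an assemblage (its utilisation proportions would involve a
#' division by zero), so such species are excluded from computation for that
#' assemblage.
#'
#' @param m a `community_matrix`.
#' @param quiet suppress the warning listing excluded species.
#' @return A `community_matrix` with the empty rows removed.
#' @export
drop_empty_species <- function(m, quiet = FALSE) {
  stopifnot(inherits(m, "community_matrix"))
  keep <- rowSums(m$abundance) > 0
  if (all(keep)) return(m)
  if (!quiet)
    warning("excluding species with zero total abundance in '", m$label, "': ",
            paste(rownames(m$abundance)[!keep], collapse = ", "),
            call. = FALSE)
  if (sum(keep) < 2L)
    .stopf("fewer than 2 species with positive abundance in '%s'", m$label)
  community_matrix(m$abundance[keep, , drop = FALSE], label = m$label)
}

## species metadata ----------------------------------------------------------

.normalize_category <- function(x) {
  y <- gsub("[ -]+", "_", tolower(trimws(x)))
  y[y == "nonstygobite"] <- "non_stygobite"
  bad <- !y %in% c("stygobite", "non_stygobite")
  if (any(bad))
    .stopf("unknown category: %s (allowed: stygobite, non_stygobite)",
           paste(unique(x[bad]), collapse = ", "))
  y
}

#' Species metadata: ecological categories
#'
#' Maps each species to one of two ecological categories: `stygobite`
#' (obligate groundwater species) or `non_stygobite`. Category tokens are
#' case-insensitive and tolerate space or hyphen separators
#' (`"Non-stygobite"` is accepted).
#'
#' @param species_id character vector of species identifiers (unique).
#' @param category character vector of categories, recycled if length 1.
#' @return A named character vector of class `species_metadata` mapping
#'   species id to category.
#' @export
species_metadata <- function(species_id, category) {
  species_id <- as.character(species_id)
  if (anyDuplicated(species_id))
    .stopf("duplicate species_id in metadata: %s",
           paste(unique(species_id[duplicated(species_id)]), collapse = ", "))
  category <- .normalize_category(rep_len(as.character(category),
                                          length(species_id)))
  structure(setNames(category, species_id), class = "species_metadata")
}

#' @rdname species_metadata
#' @param path two-column CSV (species_id, category) with a header row.
#' @export
read_species_metadata <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) .stopf("metadata CSV needs two columns (species_id, category)")
  species_metadata(df[[1L]], df[[2L]])
}

#' @export
print.species_metadata <- function(x, ...) {
  cat(sprintf("Species metadata: %d species (%d stygobites, %d non-stygobites)\n",
              length(x), sum(x == "stygobite"), sum(x == "non_stygobite")))
  invisible(x)
}

#' Select the species of one ecological category
#'
#' @param m a `community_matrix`.
#' @param meta a [species_metadata()] object covering all species of `m`.
#' @param category `"stygobite"` or `"non_stygobite"`.
#' @return `m` restricted to the requested category; an error if fewer than
#'   two such species are present.
#' @export
subset_category <- function(m, meta, category) {
  stopifnot(inherits(m, "community_matrix"), inherits(meta, "species_metadata"))
  category <- .normalize_category(category)
  missing <- setdiff(species_ids(m), names(meta))
  if (length(missing))
    .stopf("species missing from metadata: %s", paste(missing, collapse = ", "))
  keep <- species_ids(m)[meta[species_ids(m)] == category]
  if (length(keep) < 2L)
    .stopf("fewer than 2 species of category '%s' in '%s'", category, m$label)
  subset_community(m, keep)
}

## presence/absence ----------------------------------------------------------

#' Presence/absence view of a community matrix
#'
#' The C-score works on incidence data: a species is scored present in a
#' sample whenever its abundance there is positive.
#'
#' @param m a `community_matrix` (or a numeric matrix with dimnames).
#' @return An object of class `presence_matrix`: list with `label` and a
#'   binary `incidence` matrix. Thresholding is idempotent.
#' @export
to_presence <- function(m) {
  if (inherits(m, "presence_matrix")) return(m)
  if (inherits(m, "community_matrix")) {
    inc <- (m$abundance > 0) + 0
    label <- m$label
  } else {
    inc <- (as.matrix(m) > 0) + 0
    label <- "community"
  }
  structure(list(label = label, incidence = inc), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix '%s': %d species x %d samples, fill %.2f\n",
              x$label, nrow(x$incidence), ncol(x$incidence),
              mean(x$incidence)))
  invisible(x)
}

#' Mean abundance per composite sample
#'
#' Divides the total number of individuals by the number of composite samples
#' (one per site in the pooled convention).
#'
#' @param x a `community_matrix`, or a numeric total.
#' @param n_samples number of composite samples.
#' @return Mean number of individuals per sample.
#' @export
per_sample_mean <- function(x, n_samples) {
  total <- if (inherits(x, "community_matrix")) sum(x$abundance) else as.numeric(x)
  if (n_samples <= 0) .stopf("n_samples must be positive")
  total / n_samples
}
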