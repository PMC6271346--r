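# Fatty-acid profiles, isolate libraries and taxon ratio matrices.
#
# A profile is one entity's FA composition within one lipid fraction,
# normally as weight percent of summed FA. Ratio matrices express each
# taxon's FA amounts relative to 16:0 (= 1), the convention used when
# profiles feed a CHEMTAX-style unmixing.

LIPID_FRACTIONS <- c("PLFA", "neutral", "acetone_mobile", "free_fa",
                     "phospholipid", "total")
RESERVED_COLS <- c("entity_id", "lipid_fraction", "taxon")

#' Construct a fatty-acid profile
#'
#' @param entity_id Identifier of the organism/sample the profile belongs to.
#' @param values Named non-negative numeric vector; names are fatty-acid
#'   names (any accepted dialect — canonicalized on construction).
#' @param lipid_fraction One of `r paste(LIPID_FRACTIONS, collapse=", ")`.
#' @param units `"weight_pct"` (values sum to 100, checked to within 0.5) or
#'   `"mass"` (arbitrary non-negative quantities).
#' @param meta Free-form annotation list (taxon, pond code, date, mass ...).
#' @return An object of class `fa_profile`.
#' @export
fa_profile <- function(entity_id, values, lipid_fraction = "total",
                       units = "weight_pct", meta = list()) {
  stopifnot(is.numeric(values), length(values) > 0, !is.null(names(values)))
  if (!lipid_fraction %in% LIPID_FRACTIONS)
    stop("unknown lipid fraction '", lipid_fraction, "'", call. = FALSE)
  units <- match.arg(units, c("weight_pct", "mass"))
  values[is.na(values)] <- 0
  if (any(values < 0))
    stop("profile '", entity_id, "' contains negative quantities",
         call. = FALSE)
  nm <- canonicalize_fa_names(names(values))
  if (anyDuplicated(nm))
    stop("duplicate fatty-acid entries after canonicalization: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(values) <- nm
  if (units == "weight_pct" && abs(sum(values) - 100) > 0.5)
    stop("weight-percent profile '", entity_id, "' sums to ",
         format(sum(values)), ", not 100 (tolerance 0.5)", call. = FALSE)
  structure(list(entity_id = as.character(entity_id),
                 lipid_fraction = lipid_fraction,
                 values = values, units = units, meta = meta),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %s [%s, %s], %d fatty acids\n", x$entity_id,
              x$lipid_fraction, x$units, length(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Rescale a profile to weight percent
#'
#' @param p An `fa_profile`.
#' @return The profile with values summing to 100.
#' @export
as_weight_pct <- function(p) {
  stopifnot(inherits(p, "fa_profile"))
  tot <- sum(p$values)
  if (tot <= 0) stop("profile has zero total mass", call. = FALSE)
  fa_profile(p$entity_id, p$values / tot * 100, p$lipid_fraction,
             units = "weight_pct", meta = p$meta)
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read fatty-acid profiles from a CSV/TSV table
#'
#' One header row of fatty-acid names plus the reserved columns `entity_id`,
#' optionally `lipid_fraction` and `taxon`; one row per entity. Empty cells
#' are read as 0 (fatty acid not detected). Duplicate FA columns (after
#' canonicalization) and negative or non-numeric cells are rejected.
#'
#' @param path CSV (comma) or TSV (tab) file.
#' @param units Passed to [fa_profile()].
#' @param ratio_source If `TRUE`, require a 16:0 column (needed when the
#'   profiles will be normalized to 16:0).
#' @return List of `fa_profile`.
#' @export
read_profiles <- function(path, units = "weight_pct", ratio_source = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (!"entity_id" %in% names(df))
    stop("profile table must have an 'entity_id' column", call. = FALSE)
  fa_cols <- setdiff(names(df), RESERVED_COLS)
  if (!length(fa_cols)) stop("no fatty-acid columns found", call. = FALSE)
  canon <- canonicalize_fa_names(fa_cols)
  if (anyDuplicated(canon))
    stop("duplicate fatty-acid columns: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  if (ratio_source && !"16:0" %in% canon)
    stop("ratio-source table lacks a 16:0 column", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    raw <- df[i, fa_cols]
    vals <- suppressWarnings(as.numeric(unlist(raw)))
    bad <- which(is.na(vals) & !is.na(unlist(raw)) & nzchar(trimws(unlist(raw))))
    if (length(bad))
      stop("malformed numeric cell(s) in row ", i, ", column(s) ",
           paste(fa_cols[bad], collapse = ", "), call. = FALSE)
    vals[is.na(vals)] <- 0
    names(vals) <- canon
    meta <- list()
    if ("taxon" %in% names(df)) meta$taxon <- df$taxon[i]
    fa_profile(df$entity_id[i], vals,
               lipid_fraction = if ("lipid_fraction" %in% names(df))
                 df$lipid_fraction[i] else "total",
               units = units, meta = meta)
  })
}

#' Write fatty-acid profiles to CSV
#'
#' Values are written at full double precision so a read/write round trip is
#' lossless.
#'
#' @param profiles List of `fa_profile`.
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(length(profiles) > 0)
  fas <- sort(unique(unlist(lapply(profiles, function(p) names(p$values)))))
  rows <- lapply(profiles, function(p) {
    v <- setNames(numeric(length(fas)), fas)
    v[names(p$values)] <- p$values
    c(entity_id = p$entity_id, lipid_fraction = p$lipid_fraction,
      taxon = if (is.null(p$meta$taxon)) "" else p$meta$taxon,
      setNames(sprintf("%.17g", v), fas))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize a profile to a reference fatty acid
#'
#' Divides every value by the reference value so the reference maps to 1
#' (the "referred to 16:0" convention of taxon ratio matrices). Idempotent.
#'
#' @param p An `fa_profile` or a named numeric vector.
#' @param reference Reference fatty-acid name (default `"16:0"`).
#' @return Named numeric ratio vector over the profile's fatty acids.
#' @export
normalize_to_reference <- function(p, reference = "16:0") {
  v <- if (inherits(p, "fa_profile")) p$values else p
  stopifnot(is.numeric(v), !is.null(names(v)))
  ref <- canonicalize_fa_names(reference)
  if (!ref %in% names(v) || v[[ref]] <= 0)
    stop("reference fatty acid ", ref, " absent or zero in profile",
         call. = FALSE)
  v / v[[ref]]
}

#' Construct a taxon x fatty-acid ratio matrix
#'
#' Rows are taxa, columns fatty acids; every row is referenced to its 16:0
#' value, which equals exactly 1 after construction. Absent fatty acids are
#' structural zeros.
#'
#' @param values Numeric matrix (taxa in rows, FAs in columns, dimnames set).
#' @param provenance Free-text origin note.
#' @return Object of class `taxon_ratio_matrix` (a matrix with attributes).
#' @export
taxon_ratio_matrix <- function(values, provenance = "") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  colnames(values) <- canonicalize_fa_names(colnames(values))
  if (anyDuplicated(colnames(values)))
    stop("duplicate fatty-acid columns in ratio matrix", call. = FALSE)
  values[is.na(values)] <- 0
  if (any(values < 0)) stop("ratio matrix has negative entries", call. = FALSE)
  if (!"16:0" %in% colnames(values))
    stop("ratio matrix must contain a 16:0 column", call. = FALSE)
  ref <- values[, "16:0"]
  if (any(ref <= 0))
    stop("16:0 must be positive in every taxon", call. = FALSE)
  values <- sweep(values, 1, ref, "/")
  values[, "16:0"] <- 1  # exact, not within rounding
  structure(values, class = c("taxon_ratio_matrix", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.taxon_ratio_matrix <- function(x, ...) {
  cat(sprintf("<taxon_ratio_matrix> %d taxa x %d fatty acids (16:0 = 1)\n",
              nrow(x), ncol(x)))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read a ratio matrix from CSV (fatty acids as rows, taxa as columns)
#'
#' The file layout mirrors published PLFA ratio tables: first column holds
#' fatty-acid names, remaining columns one taxon each; empty cells are
#' structural zeros.
#'
#' @param path CSV path.
#' @param provenance Origin note (defaults to the file path).
#' @return A [taxon_ratio_matrix()].
#' @export
read_ratio_matrix <- function(path, provenance = path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  fa <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- fa
  taxon_ratio_matrix(t(m), provenance = provenance)
}

#' Write a ratio matrix to CSV in the fatty-acids-as-rows layout
#'
#' @param R A `taxon_ratio_matrix`.
#' @param path Output CSV path.
#' @export
write_ratio_matrix <- function(R, path) {
  stopifnot(inherits(R, "taxon_ratio_matrix"))
  df <- data.frame(fatty_acid = colnames(R),
                   apply(t(unclass(R)), 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  names(df)[-1] <- rownames(R)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a taxon ratio matrix from an isolate library
#'
#' Each taxon's signature is the arithmetic mean of its isolates' profiles
#' after normalizing each profile to 16:0 = 1. Fatty acids are dropped when
#' their mean weight percent is below `min_mean_pct` in every taxon, or
#' (optionally) when they occur (> 0) in only one taxon across the whole
#' library — both standard pre-filters for chemotaxonomic ratio tables.
#'
#' @param isolates List of `fa_profile` in weight percent, each with
#'   `meta$taxon` set.
#' @param min_mean_pct Low-abundance threshold in weight percent (default 1).
#' @param drop_single_species Drop FAs found in a single taxon (default TRUE).
#' @param provenance Origin note.
#' @return A [taxon_ratio_matrix()].
#' @export
build_ratio_matrix <- function(isolates, min_mean_pct = 1,
                               drop_single_species = TRUE,
                               provenance = "isolate library") {
  stopifnot(length(isolates) > 0)
  taxa <- vapply(isolates, function(p) {
    if (is.null(p$meta$taxon)) stop("isolate without meta$taxon", call. = FALSE)
    as.character(p$meta$taxon)
  }, character(1))
  fas <- sort(unique(unlist(lapply(isolates, function(p) names(p$values)))))
  if (!"16:0" %in% fas)
    stop("isolate library lacks 16:0, the reference fatty acid", call. = FALSE)
  W <- t(vapply(isolates, function(p) {
    v <- setNames(numeric(length(fas)), fas)
    v[names(p$values)] <- p$values
    v
  }, numeric(length(fas))))
  taxon_levels <- unique(taxa)
  # mean weight percent per taxon (on the raw weight-% scale)
  mean_pct <- vapply(taxon_levels, function(tx)
    colMeans(W[taxa == tx, , drop = FALSE]), numeric(length(fas)))
  keep <- apply(mean_pct, 1, max) >= min_mean_pct
  if (drop_single_species) {
    n_taxa_present <- vapply(seq_along(fas), function(j)
      sum(vapply(taxon_levels, function(tx)
        any(W[taxa == tx, j] > 0), logical(1))), integer(1))
    keep <- keep & n_taxa_present > 1
  }
  keep[fas == "16:0"] <- TRUE
  fas_kept <- fas[keep]
  ratios <- vapply(taxon_levels, function(tx) {
    rows <- which(taxa == tx)
    norm <- vapply(rows, function(i) {
      normalize_to_reference(W[i, ], "16:0")
    }, numeric(length(fas)))
    rowMeans(matrix(norm, nrow = length(fas)))[keep]
  }, numeric(sum(keep)))
  ratios <- t(matrix(ratios, nrow = sum(keep),
                     dimnames = list(fas_kept, taxon_levels)))
  empty <- rowSums(ratios[, setdiff(fas_kept, "16:0"), drop = FALSE]) == 0
  if (any(empty))
    stop("taxa with no surviving fatty acid besides 16:0: ",
         paste(taxon_levels[empty], collapse = ", "), call. = FALSE)
  taxon_ratio_matrix(ratios, provenance = provenance)
}

#' Construct a reference library for isolate identification
#'
#' @param profiles List of weight-percent `fa_profile`, each with
#'   `meta$taxon` set.
#' @return Object of class `reference_library`.
#' @export
reference_library <- function(profiles) {
  stopifnot(length(profiles) > 0)
  lapply(profiles, function(p) {
    stopifnot(inherits(p, "fa_profile"))
    if (is.null(p$meta$taxon))
      stop("library entry without meta$taxon", call. = FALSE)
  })
  structure(list(entries = profiles), class = "reference_library")
}

#' Identify an isolate by fatty-acid profile similarity
#'
#' Library matching in the spirit of commercial FAME identification systems:
#' profiles are compared as weight-percent vectors over the union of fatty
#' acids (absent = 0) and scored by `1 / (1 + Euclidean distance)`, so an
#' identical profile scores 1. Ranking is deterministic; ties are broken by
#' taxon label.
#'
#' @param p Query `fa_profile` (weight percent).
#' @param lib A [reference_library()].
#' @param top_k Number of matches to return.
#' @return `data.frame` with columns `taxon`, `entity_id`, `score`, best
#'   match first.
#' @export
identify_isolate <- function(p, lib, top_k = 5) {
  stopifnot(inherits(p, "fa_profile"), inherits(lib, "reference_library"))
  if (!length(lib$entries)) stop("empty reference library", call. = FALSE)
  fas <- sort(unique(c(names(p$values),
                       unlist(lapply(lib$entries, function(e) names(e$values))))))
  expand <- function(v) {
    out <- setNames(numeric(length(fas)), fas)
    out[names(v)] <- v
    out
  }
  q <- expand(p$values)
  score <- vapply(lib$entries, function(e)
    1 / (1 + sqrt(sum((q - expand(e$values))^2))), numeric(1))
  taxon <- vapply(lib$entries, function(e) as.character(e$meta$taxon),
                  character(1))
  entity <- vapply(lib$entries, function(e) e$entity_id, character(1))
  ord <- order(-score, taxon, entity)
  utils::head(data.frame(taxon = taxon[ord], entity_id = entity[ord],
                         score = score[ord], row.names = NULL), top_k)
}
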