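# Fatty-acid nomenclature: parsing, canonical spelling, classification.
#
# Names follow the shorthand used in chromatography reports:
#   <carbons>:<double bonds>[ω<position>[c|t]]   e.g. 18:1ω9c, 16:3ω4, 16:0
# with optional prefixes for iso/anteiso branches (i-15:0, a-17:0,
# "15:0 anteiso"), mid-chain methyl branches (10-Me 16:0), hydroxy acids
# (3-OH 10:0) and cyclopropyl rings (cy17:0). GC software exports vary in
# dialect (ω vs w, italics markers, "16:00" for 16:0); all are accepted and
# reduced to one canonical spelling.

OMEGA <- "ω"

#' Construct a fatty-acid descriptor
#'
#' A structured representation of one fatty acid: chain length, unsaturation,
#' omega position (first double bond counted from the methyl end), double-bond
#' geometry, branching, hydroxylation and cyclopropyl ring. The canonical name
#' is derived from the fields, so `parse_fa_name(canonical_name(d))`
#' reproduces `d` exactly.
#'
#' @param carbons Integer chain length (>= 2).
#' @param double_bonds Integer number of double bonds (>= 0).
#' @param omega Optional integer omega position; only valid when
#'   `double_bonds >= 1`.
#' @param geometry `"cis"`, `"trans"` or `NA` (unspecified); only valid when
#'   `double_bonds >= 1`. A geometry-free monounsaturate (e.g. `16:1ω8`)
#'   is distinct from its cis/trans variants.
#' @param branch `"none"`, `"iso"`, `"anteiso"` or `"methyl"`.
#' @param methyl_position Branch carbon for `branch = "methyl"` (e.g. 10 for
#'   10-Me 16:0); `NA` otherwise.
#' @param hydroxyl_position Optional integer position of a hydroxyl group
#'   (e.g. 3 for 3-OH 10:0).
#' @param cyclopropyl Logical; cyclopropyl acids are saturated by definition.
#' @return An object of class `fa_descriptor`.
#' @examples
#' fa_descriptor(16, 1, omega = 7, geometry = "cis")
#' fa_descriptor(15, 0, branch = "anteiso")
#' @export
fa_descriptor <- function(carbons, double_bonds, omega = NA_integer_,
                          geometry = NA_character_, branch = "none",
                          methyl_position = NA_integer_,
                          hydroxyl_position = NA_integer_,
                          cyclopropyl = FALSE) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  omega <- as.integer(omega)
  geometry <- as.character(geometry)
  if (is.na(carbons) || carbons < 2)
    stop("fatty acid must have at least 2 carbons", call. = FALSE)
  if (is.na(double_bonds) || double_bonds < 0)
    stop("number of double bonds must be a non-negative integer", call. = FALSE)
  if (double_bonds == 0) {
    if (!is.na(omega))
      stop("omega position requires at least one double bond", call. = FALSE)
    if (!is.na(geometry))
      stop("double-bond geometry requires at least one double bond",
           call. = FALSE)
  }
  if (!is.na(omega) && (omega < 1 || omega > carbons - 2))
    stop("omega position ", omega, " impossible for a ", carbons,
         "-carbon chain", call. = FALSE)
  if (!is.na(geometry) && !geometry %in% c("cis", "trans"))
    stop("geometry must be 'cis', 'trans' or NA", call. = FALSE)
  if (!branch %in% c("none", "iso", "anteiso", "methyl"))
    stop("branch must be one of none/iso/anteiso/methyl", call. = FALSE)
  if (branch == "iso" && carbons < 4)
    stop("iso branching requires at least 4 carbons", call. = FALSE)
  if (branch == "anteiso" && carbons < 5)
    stop("anteiso branching requires at least 5 carbons", call. = FALSE)
  if (branch == "methyl") {
    methyl_position <- as.integer(methyl_position)
    if (is.na(methyl_position) || methyl_position < 2 ||
        methyl_position > carbons - 1)
      stop("methyl branch position must lie within the chain", call. = FALSE)
  } else {
    methyl_position <- NA_integer_
  }
  if (!is.na(hydroxyl_position)) {
    hydroxyl_position <- as.integer(hydroxyl_position)
    if (hydroxyl_position < 2 || hydroxyl_position > carbons)
      stop("hydroxyl position must lie within the chain", call. = FALSE)
  } else {
    hydroxyl_position <- NA_integer_
  }
  cyclopropyl <- isTRUE(cyclopropyl)
  if (cyclopropyl && double_bonds != 0)
    stop("cyclopropyl fatty acids are saturated (0 double bonds)",
         call. = FALSE)
  d <- structure(
    list(carbons = carbons, double_bonds = double_bonds, omega = omega,
         geometry = geometry, branch = branch,
         methyl_position = methyl_position,
         hydroxyl_position = hydroxyl_position, cyclopropyl = cyclopropyl),
    class = "fa_descriptor")
  d$name <- canonical_name(d)
  d
}

#' Canonical spelling of a fatty-acid descriptor
#'
#' Deterministic single spelling: omega notation with the Greek letter,
#' `i-`/`a-` branch prefixes, `k-Me` and `k-OH` prefixes, `cy` prefix for
#' cyclopropyl acids. Round-trips through [parse_fa_name()].
#'
#' @param d An `fa_descriptor`.
#' @return Character scalar.
#' @export
canonical_name <- function(d) {
  stopifnot(inherits(d, "fa_descriptor"))
  base <- sprintf("%d:%d", d$carbons, d$double_bonds)
  if (!is.na(d$omega)) {
    base <- paste0(base, OMEGA, d$omega)
    if (!is.na(d$geometry))
      base <- paste0(base, if (d$geometry == "cis") "c" else "t")
  }
  if (d$cyclopropyl) base <- paste0("cy", base)
  if (d$branch == "iso") base <- paste0("i-", base)
  if (d$branch == "anteiso") base <- paste0("a-", base)
  if (d$branch == "methyl") base <- sprintf("%d-Me %s", d$methyl_position, base)
  if (!is.na(d$hydroxyl_position))
    base <- sprintf("%d-OH %s", d$hydroxyl_position, base)
  base
}

#' @export
print.fa_descriptor <- function(x, ...) {
  cat("<fa_descriptor>", x$name, "\n")
  cat(sprintf("  %d carbons, %d double bond(s)", x$carbons, x$double_bonds))
  if (!is.na(x$omega))
    cat(sprintf(", %s%d%s", OMEGA, x$omega,
                if (is.na(x$geometry)) "" else paste0(" (", x$geometry, ")")))
  cat("\n")
  feats <- c(
    if (x$branch != "none")
      paste0("branch: ", x$branch,
             if (x$branch == "methyl") paste0(" at C", x$methyl_position) else ""),
    if (!is.na(x$hydroxyl_position)) paste0("hydroxyl at C", x$hydroxyl_position),
    if (x$cyclopropyl) "cyclopropyl ring")
  if (length(feats)) cat(" ", paste(feats, collapse = "; "), "\n")
  invisible(x)
}

fa_parse_error <- function(name, token, why) {
  stop(sprintf("cannot parse fatty-acid name '%s': %s in token '%s'",
               name, why, token), call. = FALSE)
}

#' Parse a fatty-acid name
#'
#' Accepts the dialect variants seen in chromatography exports:
#' `"18:1ω9c"` and `"18:1w9c"`; `"i-15:0"`, `"*i*-15:0"`, `"iso-15:0"` and
#' `"15:0 iso"`; double-zero saturates (`"16:00"` read as `"16:0"`);
#' `"10-Me 16:0"`; `"3-OH 10:0"`; `"cy19:0"`. Prefix matching is
#' case-insensitive and italics markers are stripped.
#'
#' @param name A single non-empty fatty-acid name.
#' @return An [fa_descriptor()].
#' @examples
#' parse_fa_name("18:1ω9c")
#' parse_fa_name("15:0 anteiso")$name   # "a-15:0"
#' @export
parse_fa_name <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("fatty-acid name must be a single non-empty string", call. = FALSE)
  orig <- name
  s <- gsub("\\*", "", name)            # italics markers
  s <- gsub(OMEGA, "w", s)              # unify omega spelling
  s <- gsub("\\s+", " ", trimws(s))
  low <- tolower(s)

  hydroxyl <- NA_integer_
  branch <- "none"
  methyl_pos <- NA_integer_
  cyclo <- FALSE

  # optional hydroxy prefix: "3-OH " / "3OH "
  m <- regmatches(low, regexec("^([0-9]+)-?oh ?(.+)$", low))[[1]]
  if (length(m)) {
    hydroxyl <- as.integer(m[2])
    low <- m[3]
  }
  # optional methyl-branch prefix: "10-Me " / "10Me"
  m <- regmatches(low, regexec("^([0-9]+)-?me ?(.+)$", low))[[1]]
  if (length(m)) {
    branch <- "methyl"
    methyl_pos <- as.integer(m[2])
    low <- m[3]
  }
  # iso/anteiso prefix: "i-", "a-", "iso-", "anteiso-", "iso 15:0"
  m <- regmatches(low, regexec("^(iso|anteiso|i|a)[- ](.+)$", low))[[1]]
  if (length(m)) {
    if (branch != "none")
      fa_parse_error(orig, m[2], "conflicting branch specifications")
    branch <- switch(m[2], i = , iso = "iso", a = , anteiso = "anteiso")
    low <- m[3]
  }
  # iso/anteiso suffix: "15:0 iso"
  m <- regmatches(low, regexec("^(.+) (iso|anteiso)$", low))[[1]]
  if (length(m)) {
    if (branch != "none")
      fa_parse_error(orig, m[3], "conflicting branch specifications")
    branch <- m[3]
    low <- m[2]
  }
  # cyclopropyl prefix: "cy17:0", "cy-17:0"
  m <- regmatches(low, regexec("^cy-?(.+)$", low))[[1]]
  if (length(m)) {
    cyclo <- TRUE
    low <- m[2]
  }
  low <- trimws(low)
  m <- regmatches(low,
                  regexec("^([0-9]+):([0-9]+)(w([0-9]+)([ct])?)?$", low))[[1]]
  if (!length(m))
    fa_parse_error(orig, low, "not of the form <carbons>:<double bonds>[w<n>[c|t]]")
  carbons <- as.integer(m[2])
  db_tok <- m[3]
  db <- as.integer(db_tok)
  # "16:00" is the double-zero spelling of the saturate 16:0; but "18:10"
  # (ten double bonds) is rejected as a typo rather than silently read.
  if (nchar(db_tok) > 1L && db != 0L)
    fa_parse_error(orig, db_tok, "ambiguous multi-digit double-bond count")
  omega <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  geometry <- if (nzchar(m[6])) c(c = "cis", t = "trans")[[m[6]]] else NA_character_
  if (db > floor(carbons / 2))
    fa_parse_error(orig, low, "more double bonds than the chain can hold")
  tryCatch(
    fa_descriptor(carbons, db, omega = omega, geometry = geometry,
                  branch = branch, methyl_position = methyl_pos,
                  hydroxyl_position = hydroxyl, cyclopropyl = cyclo),
    error = function(e) fa_parse_error(orig, low, conditionMessage(e)))
}

#' Parse several fatty-acid names to canonical spellings
#'
#' @param names Character vector of fatty-acid names.
#' @return Character vector of canonical names (same length).
#' @export
canonicalize_fa_names <- function(names) {
  vapply(names, function(nm) parse_fa_name(nm)$name, character(1),
         USE.NAMES = FALSE)
}

#' Classify a fatty acid into marker-relevant categories
#'
#' Category tags: `SAFA`/`MUFA`/`PUFA` by unsaturation (PUFA means two or
#' more double bonds), `C16_PUFA` and `C18_PUFA` (the autotroph marker
#' classes), `iso_anteiso`, `hydroxy`, `cyclopropyl`, `methyl_branched`, and
#' `short_chain_lt14` (chains under 14 carbons, conventionally excluded from
#' diet-tracing analyses because consumers synthesise them de novo).
#'
#' @param d An `fa_descriptor`, or a name parseable by [parse_fa_name()].
#' @return Character vector of tags.
#' @examples
#' classify_fa("16:3ω4")  # PUFA, C16_PUFA
#' classify_fa("cy17:0")       # SAFA, cyclopropyl
#' @export
classify_fa <- function(d) {
  if (is.character(d)) d <- parse_fa_name(d)
  stopifnot(inherits(d, "fa_descriptor"))
  tags <- character(0)
  tags <- c(tags,
            if (d$double_bonds == 0) "SAFA"
            else if (d$double_bonds == 1) "MUFA" else "PUFA")
  if (d$double_bonds >= 2 && d$carbons == 16) tags <- c(tags, "C16_PUFA")
  if (d$double_bonds >= 2 && d$carbons == 18) tags <- c(tags, "C18_PUFA")
  if (d$branch %in% c("iso", "anteiso")) tags <- c(tags, "iso_anteiso")
  if (!is.na(d$hydroxyl_position)) tags <- c(tags, "hydroxy")
  if (d$cyclopropyl) tags <- c(tags, "cyclopropyl")
  if (d$branch == "methyl") tags <- c(tags, "methyl_branched")
  if (d$carbons < 14) tags <- c(tags, "short_chain_lt14")
  tags
}
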