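# Trophic marker sums and retention ratios.
#
# Group contributions (bacteria / fungi / autotrophs) are quantified as the
# summed weight percent of each group's marker fatty acids; retention ratios
# compare a consumer's share of selected fatty acids (by default the
# essential omega-3 PUFAs EPA 20:5w3 and DHA 22:6w3) with their share in the
# seston it feeds on.

MARKER_GROUPS <- c("bacteria", "fungi", "autotrophs")

#' Construct a marker scheme
#'
#' An ordered rule list mapping fatty acids to one of the groups bacteria,
#' fungi or autotrophs. Each rule matches either an explicit fatty-acid name
#' (`match = "name"`; double-bond geometry is ignored so `16:1ω5c`
#' satisfies the fungal marker `16:1ω5`) or a classification category from
#' [classify_fa()] (`match = "category"`, e.g. `iso_anteiso`, `C16_PUFA`).
#' The first matching rule wins, so every fatty acid maps to at most one
#' group; unmatched fatty acids carry no group signal.
#'
#' @param rules `data.frame` with columns `order`, `group`, `match`, `value`.
#' @return Object of class `marker_scheme`.
#' @export
marker_scheme <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("order", "group", "match", "value") %in% names(rules)))
  if (!all(rules$group %in% MARKER_GROUPS))
    stop("marker groups must be among: ",
         paste(MARKER_GROUPS, collapse = ", "), call. = FALSE)
  if (!all(rules$match %in% c("name", "category")))
    stop("rule match type must be 'name' or 'category'", call. = FALSE)
  rules <- rules[order(rules$order), , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(rules = rules), class = "marker_scheme")
}

#' @export
print.marker_scheme <- function(x, ...) {
  cat("<marker_scheme>", nrow(x$rules), "rules (first match wins)\n")
  print(x$rules)
  invisible(x)
}

#' Read a marker scheme from its CSV representation
#'
#' @param path CSV with columns `order,group,match,value`.
#' @return A [marker_scheme()].
#' @export
read_marker_scheme <- function(path) {
  marker_scheme(utils::read.csv(path, stringsAsFactors = FALSE,
                                fileEncoding = "UTF-8"))
}

#' The default freshwater plankton marker scheme
#'
#' Fungi: 16:1ω5. Bacteria: straight-chain 15:0, all iso/anteiso branched
#' FAs, hydroxy FAs, cyclopropyl FAs and 18:1ω8 (type II methanotrophs).
#' Autotrophs: C16 and C18 PUFAs. Straight-chain odd FAs other than 15:0 are
#' deliberately not markers (the enumeration is exhaustive).
#'
#' @return A [marker_scheme()].
#' @export
default_marker_scheme <- function() {
  read_marker_scheme(system.file("extdata", "marker_scheme.csv",
                                 package = "plfatax"))
}

name_rule_matches <- function(d, value) {
  ref <- parse_fa_name(value)
  d$carbons == ref$carbons && d$double_bonds == ref$double_bonds &&
    identical(d$omega, ref$omega) && d$branch == ref$branch &&
    identical(d$hydroxyl_position, ref$hydroxyl_position) &&
    d$cyclopropyl == ref$cyclopropyl
  # geometry deliberately not compared
}

#' Assign a fatty acid to its marker group
#'
#' @param fa An `fa_descriptor` or fatty-acid name.
#' @param scheme A [marker_scheme()].
#' @return `"bacteria"`, `"fungi"`, `"autotrophs"` or `NA_character_`.
#' @export
assign_marker_group <- function(fa, scheme = default_marker_scheme()) {
  if (is.character(fa)) fa <- parse_fa_name(fa)
  stopifnot(inherits(fa, "fa_descriptor"), inherits(scheme, "marker_scheme"))
  tags <- classify_fa(fa)
  for (i in seq_len(nrow(scheme$rules))) {
    r <- scheme$rules[i, ]
    hit <- if (r$match == "name") name_rule_matches(fa, r$value)
           else r$value %in% tags
    if (hit) return(r$group)
  }
  NA_character_
}

#' Marker-group proportions of a profile
#'
#' Sums the weight percent of each group's marker fatty acids. With
#' `relative = TRUE` (the default) the three sums are renormalized to
#' fractions of total marker mass; with `relative = FALSE` the raw summed
#' weight percentages are returned (both readings of "group proportion" are
#' used in the literature). Scale-invariant in the relative mode.
#'
#' @param p An `fa_profile`.
#' @param scheme A [marker_scheme()].
#' @param relative Renormalize over the three groups (default `TRUE`).
#' @return Named numeric vector over bacteria/fungi/autotrophs.
#' @export
marker_proportions <- function(p, scheme = default_marker_scheme(),
                               relative = TRUE) {
  stopifnot(inherits(p, "fa_profile"))
  groups <- vapply(names(p$values),
                   function(nm) assign_marker_group(nm, scheme), character(1))
  out <- setNames(numeric(length(MARKER_GROUPS)), MARKER_GROUPS)
  for (g in MARKER_GROUPS) out[g] <- sum(p$values[!is.na(groups) & groups == g])
  if (relative) {
    tot <- sum(out)
    if (tot <= 0)
      stop("profile '", p$entity_id, "' has zero total marker mass",
           call. = FALSE)
    out <- out / tot
  }
  out
}

#' Pool lipid fractions of one entity into a single profile
#'
#' Mass-weighted mean of the weight-percent compositions of the requested
#' fractions (e.g. neutral + acetone-mobile + free fatty acids, the reserve
#' lipid pool). Weights default to each profile's `meta$mass` and must be
#' supplied one per requested fraction otherwise.
#'
#' @param profiles List of `fa_profile` from a single entity.
#' @param which Character vector of lipid fractions to pool.
#' @param weights Optional named numeric vector of fraction masses.
#' @return A pooled `fa_profile` (lipid fraction `"total"`).
#' @export
combine_lipid_fractions <- function(profiles, which, weights = NULL) {
  stopifnot(length(profiles) > 0, length(which) > 0)
  ids <- unique(vapply(profiles, function(p) p$entity_id, character(1)))
  if (length(ids) != 1)
    stop("profiles must all belong to one entity", call. = FALSE)
  fracs <- vapply(profiles, function(p) p$lipid_fraction, character(1))
  missing <- setdiff(which, fracs)
  if (length(missing))
    stop("missing lipid fraction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sel <- profiles[match(which, fracs)]
  if (is.null(weights)) {
    weights <- vapply(sel, function(p) {
      if (is.null(p$meta$mass))
        stop("no meta$mass on fraction '", p$lipid_fraction,
             "' and no weights supplied", call. = FALSE)
      as.numeric(p$meta$mass)
    }, numeric(1))
  } else {
    if (!is.null(names(weights))) weights <- weights[which]
    stopifnot(length(weights) == length(which), all(weights >= 0),
              sum(weights) > 0)
  }
  fas <- sort(unique(unlist(lapply(sel, function(p) names(p$values)))))
  pooled <- setNames(numeric(length(fas)), fas)
  for (i in seq_along(sel)) {
    v <- setNames(numeric(length(fas)), fas)
    v[names(sel[[i]]$values)] <- sel[[i]]$values
    pooled <- pooled + weights[i] * v
  }
  pooled <- pooled / sum(weights)
  fa_profile(ids, pooled, lipid_fraction = "total",
             units = sel[[1]]$units, meta = sel[[1]]$meta)
}

#' Retention ratio of selected fatty acids in a consumer relative to seston
#'
#' The consumer-to-seston ratio of the summed share of `fa_set` (default
#' EPA + DHA). A ratio above 1 indicates selective retention/accumulation of
#' those fatty acids by the consumer.
#'
#' @param consumer Consumer `fa_profile` (weight percent).
#' @param seston Seston `fa_profile` (weight percent).
#' @param fa_set Fatty-acid names to sum (default `c("20:5ω3", "22:6ω3")`).
#' @return Numeric ratio.
#' @export
retention_ratio <- function(consumer, seston,
                            fa_set = c("20:5ω3", "22:6ω3")) {
  stopifnot(inherits(consumer, "fa_profile"), inherits(seston, "fa_profile"),
            length(fa_set) > 0)
  fa_set <- canonicalize_fa_names(fa_set)
  share <- function(p) {
    tot <- sum(p$values)
    if (tot <= 0) stop("profile with zero total", call. = FALSE)
    sum(p$values[intersect(fa_set, names(p$values))]) / tot
  }
  s_seston <- share(seston)
  if (s_seston <= 0)
    stop("seston content of the requested fatty acids is zero; ",
         "retention ratio undefined", call. = FALSE)
  share(consumer) / s_seston
}
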