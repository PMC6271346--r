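# Ordination statistics: Spearman rank correlation, Kaiser-Meyer-Olkin
# sampling adequacy, communalities, and the variable-screening pipeline
# applied to fatty-acid tables before PCA.

#' Spearman rank correlation with a two-sided t-approximation p-value
#'
#' Average ranks are used for ties; the p-value is the asymptotic
#' t approximation (appropriate for tied data, where the exact permutation
#' null is unavailable).
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @return List with `r` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Per-variable MSA from the correlation and partial-correlation (anti-image)
#' matrices: `KMO_j = sum(r^2) / (sum(r^2) + sum(q^2))` over the other
#' variables, where `q` are partial correlations obtained from the inverse
#' correlation matrix. A Moore-Penrose inverse is used when the correlation
#' matrix is singular.
#'
#' @param x Numeric matrix or data frame (observations x variables).
#' @return List with `per_variable` (named vector) and `overall`.
#' @export
kmo <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  R <- stats::cor(x)
  Rinv <- tryCatch(solve(R), error = function(e) MASS::ginv(R))
  D <- diag(1 / sqrt(abs(diag(Rinv))))
  Q <- -D %*% Rinv %*% D   # partial correlations, off-diagonal
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- colSums(R0^2)
  q2 <- colSums(Q^2)
  per <- r2 / (r2 + q2)
  names(per) <- colnames(x)
  list(per_variable = per, overall = sum(r2) / (sum(r2) + sum(q2)))
}

# Correlation-scale PCA loadings and communalities over the components
# retained by the Kaiser rule (eigenvalue > 1).
pca_communalities <- function(x) {
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  m <- max(1L, sum(ev > 1))
  L <- pc$rotation[, seq_len(m), drop = FALSE] %*%
    diag(pc$sdev[seq_len(m)], m, m)
  setNames(rowSums(L^2), colnames(x))
}

#' Screen fatty-acid variables before PCA
#'
#' Applies, in order: (1) removal of fatty acids with fewer than 14 carbons
#' (possible de novo biosynthesis in consumers, uninformative about diet);
#' (2) iterative removal, worst first, of variables failing the
#' Kaiser-Meyer-Olkin sampling-adequacy threshold; (3) iterative removal of
#' variables whose communality on the Kaiser-retained components
#' (eigenvalue > 1) does not exceed the communality threshold. Variables are
#' scaled by their standard deviation (correlation-matrix PCA) throughout.
#'
#' @param data Numeric matrix or data frame, entities x fatty acids, with
#'   fatty-acid names as column names. At least 3 entities.
#' @param kmo_threshold KMO cut-off (default 0.50, strict inequality).
#' @param communality_threshold Communality cut-off (default 0.50, strict
#'   inequality).
#' @return Object of class `pca_screen_report` with elements
#'   `removed_short_chain`, `removed_kmo`, `removed_communality`, `retained`,
#'   `kmo_values` and `communalities` (both on the final retained set).
#' @export
pca_screen <- function(data, kmo_threshold = 0.50,
                       communality_threshold = 0.50) {
  x <- as.matrix(data)
  stopifnot(!is.null(colnames(x)), nrow(x) >= 3)
  carbons <- vapply(colnames(x), function(nm) parse_fa_name(nm)$carbons,
                    integer(1))
  removed_short <- colnames(x)[carbons < 14]
  x <- x[, carbons >= 14, drop = FALSE]
  fail <- function(n_left) stop("fewer than 2 fatty acids survive screening",
                                call. = FALSE)
  if (ncol(x) < 2) fail()
  const <- apply(x, 2, stats::sd) == 0
  if (any(const))
    stop("constant fatty-acid column(s): ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)

  removed_kmo <- character(0)
  repeat {
    k <- kmo(x)$per_variable
    bad <- k <= kmo_threshold
    if (!any(bad)) break
    worst <- names(which.min(k))
    removed_kmo <- c(removed_kmo, worst)
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
    if (ncol(x) < 2) fail()
  }
  removed_comm <- character(0)
  repeat {
    h <- pca_communalities(x)
    bad <- h <= communality_threshold
    if (!any(bad)) break
    worst <- names(which.min(h))
    removed_comm <- c(removed_comm, worst)
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
    if (ncol(x) < 2) fail()
  }
  structure(list(removed_short_chain = removed_short,
                 removed_kmo = removed_kmo,
                 removed_communality = removed_comm,
                 retained = colnames(x),
                 kmo_values = kmo(x)$per_variable,
                 communalities = pca_communalities(x)),
            class = "pca_screen_report")
}

#' @export
print.pca_screen_report <- function(x, ...) {
  cat("<pca_screen_report>\n")
  cat("  removed (<14 carbons): ",
      paste(x$removed_short_chain, collapse = ", "), "\n")
  cat("  removed (KMO):         ",
      paste(x$removed_kmo, collapse = ", "), "\n")
  cat("  removed (communality): ",
      paste(x$removed_communality, collapse = ", "), "\n")
  cat("  retained:              ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of a (screened) fatty-acid table
#'
#' Standard principal component analysis on SD-scaled data. Component signs
#' are fixed by making each component's largest-magnitude loading positive,
#' so results are reproducible across platforms. Rank-deficient data yield
#' trailing zero eigenvalues rather than an error.
#'
#' @param data Numeric matrix or data frame, entities x variables.
#' @return List with `eigenvalues`, `explained_pct` (sums to 100),
#'   `loadings` (correlation-scale), `scores`.
#' @export
pca_fa <- function(data) {
  x <- as.matrix(data)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ev[ev < .Machine$double.eps * max(ev)] <- 0
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  loadings <- rot %*% diag(sqrt(ev), length(ev), length(ev))
  dimnames(loadings) <- dimnames(rot)
  list(eigenvalues = ev,
       explained_pct = 100 * ev / sum(ev),
       loadings = loadings,
       scores = scores)
}
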