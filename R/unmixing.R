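# CHEMTAX-style unmixing of sample fatty-acid compositions.
#
# Model: each sample composition (as proportions of total measured FA) is a
# convex mixture of taxon signatures, the row-normalized rows of a taxon x FA
# ratio matrix. Abundances are estimated per sample by sum-constrained
# non-negative least squares; the ratio matrix itself is then adjusted by
# projected steepest descent within multiplicative element-wise bounds
# (default +-50%), alternating until the fit stops improving. Structural
# zeros are never adjusted and the 16:0 reference entries stay frozen at 1.

#' Construct a sample x fatty-acid composition matrix
#'
#' @param values Non-negative numeric matrix, samples in rows (rownames =
#'   sample ids), fatty acids in columns.
#' @param location Optional character vector (one per sample) assigning each
#'   sample to a location group; defaults to a single group `"all"`.
#' @return Object of class `sample_matrix`.
#' @export
sample_matrix <- function(values, location = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  colnames(values) <- canonicalize_fa_names(colnames(values))
  values[is.na(values)] <- 0
  if (any(values < 0)) stop("negative sample quantities", call. = FALSE)
  if (any(rowSums(values) <= 0))
    stop("every sample row must be nonzero", call. = FALSE)
  if (is.null(location)) location <- rep("all", nrow(values))
  stopifnot(length(location) == nrow(values))
  structure(values, class = c("sample_matrix", "matrix", "array"),
            location = setNames(as.character(location), rownames(values)))
}

#' Configuration for the unmixing engine
#'
#' @param bound_factor Multiplicative bound on each nonzero ratio element
#'   (default 1.5, i.e. adjustments up to +-50% of the input value).
#' @param step_init Initial descent step as a fraction of each element's
#'   magnitude (default 0.05).
#' @param tol Relative RMSE improvement below which iteration stops
#'   (default 1e-8).
#' @param max_iter Maximum alternating iterations (default 500).
#' @param n_successive_runs Runs chained by [successive_runs()] (default 8).
#' @param n_random_starts Perturbed starts used by [randomized_starts()]
#'   (default 60).
#' @param best_fraction Fraction of the best starts averaged (default 0.1).
#' @param seed Seed for the randomized-starts perturbations.
#' @param fa_weights Optional named per-FA residual weights (default equal).
#' @return Object of class `unmix_config`.
#' @export
unmix_config <- function(bound_factor = 1.5, step_init = 0.05, tol = 1e-8,
                         max_iter = 500, n_successive_runs = 8,
                         n_random_starts = 60, best_fraction = 0.1,
                         seed = 1, fa_weights = NULL) {
  stopifnot(bound_factor >= 1, bound_factor <= 2, step_init > 0, tol > 0,
            max_iter >= 1,
            n_successive_runs >= 1, n_random_starts >= 1,
            best_fraction > 0, best_fraction <= 1)
  structure(list(bound_factor = bound_factor, step_init = step_init,
                 tol = tol, max_iter = max_iter,
                 n_successive_runs = n_successive_runs,
                 n_random_starts = n_random_starts,
                 best_fraction = best_fraction, seed = seed,
                 fa_weights = fa_weights),
            class = "unmix_config")
}

# Row-normalize taxon signatures to proportions of total FA.
# (column-major recycling of 1/rowSums is an exact row scaling)
row_norm_signatures <- function(R) {
  rs <- rowSums(R)
  if (any(rs <= 0)) stop("taxon with all-zero signature", call. = FALSE)
  R * (1 / rs)
}

# Simplex-constrained NNLS: min ||diag(sqrt(w)) (F'a - s)|| s.t. a >= 0,
# sum(a) = 1 (enforced through a heavily weighted augmentation row, then
# renormalized exactly). F is taxa x FA with rows summing to 1, s a
# proportion vector. The objective is convex, so the optimum is global.
solve_simplex_nnls <- function(Fmat, s, w = NULL, lambda = 1e4) {
  sw <- if (is.null(w)) rep(1, length(s)) else sqrt(w)
  C <- rbind(t(Fmat) * sw, rep(lambda, nrow(Fmat)))
  d <- c(s * sw, lambda)
  a <- .nnls_solve(C, d)[, 1]
  a / sum(a)
}

#' Estimate taxon abundances for one sample composition
#'
#' Fits the sample (as proportions of total measured FA) as a non-negative
#' combination of the row-normalized taxon signatures, constrained to the
#' unit simplex, and returns the abundance vector with its residual RMSE.
#'
#' @param R A [taxon_ratio_matrix()] (or plain taxa x FA matrix).
#' @param s Named non-negative numeric vector: one sample's composition.
#' @param fa_weights Optional named per-FA residual weights.
#' @return List with `abundances` (named, sums to 1), `rmse`, and `fas`
#'   (the shared fatty acids used).
#' @export
solve_abundances <- function(R, s, fa_weights = NULL) {
  stopifnot(is.matrix(R), is.numeric(s), !is.null(names(s)))
  names(s) <- canonicalize_fa_names(names(s))
  shared <- intersect(colnames(R), names(s))
  if (length(shared) < 3)
    stop("fewer than 3 fatty acids shared between ratio matrix and sample",
         call. = FALSE)
  sv <- s[shared]
  if (sum(sv) <= 0) stop("all-zero sample over shared fatty acids",
                         call. = FALSE)
  sv <- sv / sum(sv)
  Fmat <- row_norm_signatures(unclass(R)[, shared, drop = FALSE])
  w <- if (is.null(fa_weights)) NULL else {
    fw <- fa_weights[shared]
    fw[is.na(fw)] <- 1
    fw
  }
  a <- solve_simplex_nnls(Fmat, sv, w)
  resid <- as.vector(crossprod(Fmat, a)) - sv
  list(abundances = setNames(a, rownames(R)),
       rmse = sqrt(mean(if (is.null(w)) resid^2 else w * resid^2)),
       fas = shared)
}

# Weighted RMSE between reconstruction A %*% rownorm(R) and S (both as
# proportions). A is held fixed by callers during the ratio step.
unmix_objective <- function(R, A, S, w = NULL) {
  E <- A %*% row_norm_signatures(R) - S
  if (!is.null(w)) E <- E * rep(sqrt(w), each = nrow(E))
  sqrt(sum(E * E) / length(E))
}

new_unmix_result <- function(A, R, rmse, n_iter, converged, history,
                             provenance) {
  ratio_out <- if ("16:0" %in% colnames(R))
    taxon_ratio_matrix(R, provenance = provenance) else R
  structure(list(abundances = A, ratio_out = ratio_out, rmse = rmse,
                 n_iter = n_iter, converged = converged,
                 rmse_history = history),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> %d samples x %d taxa; RMSE %.3g after %d iteration(s)%s\n",
              nrow(x$abundances), ncol(x$abundances), x$rmse, x$n_iter,
              if (x$converged) " (converged)" else " (not converged)"))
  print(round(x$abundances, 3))
  invisible(x)
}

#' Fit taxon abundances with bounded ratio-matrix optimization
#'
#' Alternating optimization: (i) per-sample simplex-constrained non-negative
#' least squares for abundances given the current ratio matrix; (ii) a
#' projected steepest-descent step on the nonzero, non-reference elements of
#' the ratio matrix within `[(2 - bound_factor) * R0, bound_factor * R0]`
#' (i.e. adjustments of up to +-50% at the default 1.5), using a
#' finite-difference gradient and a halving backtracking line search so the
#' RMSE never increases. Stops when the relative RMSE improvement falls
#' below `tol` or after `max_iter` iterations; non-convergence is reported
#' through the `converged` flag, never as an error. With
#' `bound_factor = 1` the ratio matrix is returned unchanged and the result
#' equals plain [solve_abundances()] applied per sample.
#'
#' Fatty acids present in the samples but absent from the ratio matrix carry
#' no taxon information under the model and are dropped with a warning.
#'
#' @param S A [sample_matrix()].
#' @param R0 Input [taxon_ratio_matrix()].
#' @param cfg An [unmix_config()].
#' @return An `unmix_result`: `abundances` (samples x taxa, rows sum to 1),
#'   `ratio_out`, `rmse`, `n_iter`, `converged`, `rmse_history`.
#' @export
chemtax_fit <- function(S, R0, cfg = unmix_config()) {
  stopifnot(inherits(S, "sample_matrix"), is.matrix(R0),
            inherits(cfg, "unmix_config"))
  shared <- intersect(colnames(R0), colnames(S))
  extra <- setdiff(colnames(S), colnames(R0))
  if (length(extra))
    warning("dropping sample fatty acids absent from the ratio matrix: ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (length(shared) < 3)
    stop("fewer than 3 shared fatty acids", call. = FALSE)
  Sm <- unclass(S)[, shared, drop = FALSE]
  Sm <- sweep(Sm, 1, rowSums(Sm), "/")
  R_cur <- unclass(R0)[, shared, drop = FALSE]
  w <- if (is.null(cfg$fa_weights)) NULL else {
    fw <- cfg$fa_weights[shared]; fw[is.na(fw)] <- 1; fw
  }
  free <- R_cur > 0
  if ("16:0" %in% shared) free[, "16:0"] <- FALSE
  # "+-50%" is symmetric on the multiplicative factor: [0.5 r0, 1.5 r0]
  lower <- pmax(0, R_cur * (2 - cfg$bound_factor))
  upper <- R_cur * cfg$bound_factor

  solve_A <- function(R) {
    Fmat <- row_norm_signatures(R)
    t(vapply(seq_len(nrow(Sm)),
             function(i) solve_simplex_nnls(Fmat, Sm[i, ], w),
             numeric(nrow(R))))
  }

  A <- solve_A(R_cur)
  rmse <- unmix_objective(R_cur, A, Sm, w)
  history <- rmse
  converged <- FALSE
  iter <- 0L
  idx_free <- which(free)
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    if (rmse < 1e-10) {           # already at numerically exact fit
      converged <- TRUE
      break
    }
    if (cfg$bound_factor > 1 && length(idx_free)) {
      # finite-difference gradient with abundances held fixed
      base <- unmix_objective(R_cur, A, Sm, w)
      grad <- numeric(length(idx_free))
      for (k in seq_along(idx_free)) {
        j <- idx_free[k]
        h <- 1e-6 * (abs(R_cur[j]) + 1e-8)
        Rp <- R_cur
        Rp[j] <- R_cur[j] + h
        grad[k] <- (unmix_objective(Rp, A, Sm, w) - base) / h
      }
      gmax <- max(abs(grad))
      if (gmax > 0) {
        step <- numeric(length(R_cur))
        dim(step) <- dim(R_cur)
        step[idx_free] <- -cfg$step_init * R_cur[idx_free] * grad / gmax
        # backtracking (halving) line search, with expansion: once an
        # improving step is found, keep doubling while the objective drops
        t_bt <- 1
        found <- FALSE
        for (bt in seq_len(20)) {
          R_try <- pmin(pmax(R_cur + t_bt * step, lower), upper)
          o_try <- unmix_objective(R_try, A, Sm, w)
          if (o_try <= base) {
            found <- TRUE
            break
          }
          t_bt <- t_bt / 2
        }
        if (found) {
          R_best <- R_try
          o_best <- o_try
          for (ex in seq_len(8)) {
            t_bt <- 2 * t_bt
            R_try <- pmin(pmax(R_cur + t_bt * step, lower), upper)
            o_try <- unmix_objective(R_try, A, Sm, w)
            if (o_try >= o_best) break
            R_best <- R_try
            o_best <- o_try
          }
          R_cur <- R_best
        }
      }
    }
    A <- solve_A(R_cur)
    rmse_new <- unmix_objective(R_cur, A, Sm, w)
    history <- c(history, rmse_new)
    rel <- (rmse - rmse_new) / max(rmse, .Machine$double.xmin)
    rmse <- rmse_new
    if (rmse < 1e-10 || (rel >= 0 && rel < cfg$tol)) {
      converged <- TRUE
      break
    }
  }
  dimnames(A) <- list(rownames(Sm), rownames(R_cur))
  new_unmix_result(A, R_cur, rmse, iter, converged, history,
                   provenance = "chemtax_fit output")
}

#' Successive-run ratio optimization
#'
#' Chains [chemtax_fit()] runs, feeding each run's optimized ratio matrix in
#' as the next run's input (each run's bounds are taken relative to its own
#' input). Returns the run with the lowest RMSE; the RMSE sequence over runs
#' is attached as `run_rmse`.
#'
#' @inheritParams chemtax_fit
#' @return An `unmix_result` with an extra `run_rmse` element.
#' @export
successive_runs <- function(S, R0, cfg = unmix_config()) {
  R_in <- R0
  best <- NULL
  run_rmse <- numeric(0)
  for (r in seq_len(cfg$n_successive_runs)) {
    res <- chemtax_fit(S, R_in, cfg)
    run_rmse <- c(run_rmse, res$rmse)
    if (is.null(best) || res$rmse < best$rmse) best <- res
    R_in <- res$ratio_out
  }
  best$run_rmse <- run_rmse
  best
}

#' Randomized-start ratio optimization
#'
#' Generates `n_random_starts` perturbed input matrices (every nonzero,
#' non-reference element multiplied by a seeded uniform factor within the
#' bound), fits each, averages the ratio matrices of the best
#' `best_fraction` of starts by RMSE, and refits once from that mean matrix.
#' Fully reproducible under a fixed `cfg$seed`.
#'
#' @inheritParams chemtax_fit
#' @return An `unmix_result` with an extra `start_rmse` element (all starts).
#' @export
randomized_starts <- function(S, R0, cfg = unmix_config()) {
  shared <- intersect(colnames(R0), colnames(S))
  R_base <- unclass(R0)[, shared, drop = FALSE]
  free <- R_base > 0
  if ("16:0" %in% shared) free[, "16:0"] <- FALSE
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  fits <- vector("list", cfg$n_random_starts)
  for (i in seq_len(cfg$n_random_starts)) {
    R_i <- R_base
    R_i[free] <- R_base[free] *
      stats::runif(sum(free), 2 - cfg$bound_factor, cfg$bound_factor)
    if ("16:0" %in% shared) R_i[, "16:0"] <- R_base[, "16:0"]
    fits[[i]] <- chemtax_fit(S, taxon_ratio_matrix(R_i, "perturbed start"),
                             cfg)
  }
  start_rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  k <- max(1L, ceiling(cfg$best_fraction * cfg$n_random_starts))
  best_idx <- order(start_rmse)[seq_len(k)]
  R_mean <- Reduce(`+`, lapply(fits[best_idx],
                               function(f) unclass(f$ratio_out))) / k
  final <- chemtax_fit(S, taxon_ratio_matrix(R_mean, "mean of best starts"),
                       cfg)
  final$start_rmse <- start_rmse
  final
}

#' Unmix per location with location-specific taxon subsets
#'
#' Runs an independent fit for each location group using only the taxa known
#' to occur there; the merged abundance table reports excluded taxa as
#' exact zeros.
#'
#' @param S A [sample_matrix()] whose `location` attribute assigns samples
#'   to groups.
#' @param R0 Input [taxon_ratio_matrix()] covering all taxa.
#' @param membership Named list: location -> character vector of taxa.
#' @param cfg An [unmix_config()].
#' @param method One of `"fit"`, `"successive"`, `"random_starts"`.
#' @return List with `abundances` (all samples x all taxa) and
#'   `per_location` (one `unmix_result` per location).
#' @export
run_by_location <- function(S, R0, membership, cfg = unmix_config(),
                            method = c("fit", "successive", "random_starts")) {
  method <- match.arg(method)
  loc <- attr(S, "location")
  locs <- unique(loc)
  missing_loc <- setdiff(locs, names(membership))
  if (length(missing_loc))
    stop("no taxon subset for location(s): ",
         paste(missing_loc, collapse = ", "), call. = FALSE)
  A_all <- matrix(0, nrow(S), nrow(R0),
                  dimnames = list(rownames(S), rownames(R0)))
  per_loc <- list()
  runner <- switch(method, fit = chemtax_fit, successive = successive_runs,
                   random_starts = randomized_starts)
  for (l in locs) {
    taxa <- membership[[l]]
    if (!length(taxa)) stop("empty taxon subset for location ", l,
                            call. = FALSE)
    if (!all(taxa %in% rownames(R0)))
      stop("unknown taxa for location ", l, ": ",
           paste(setdiff(taxa, rownames(R0)), collapse = ", "), call. = FALSE)
    rows <- which(loc == l)
    R_sub <- unclass(R0)[taxa, , drop = FALSE]
    keep_fa <- colSums(R_sub) > 0 | colnames(R_sub) == "16:0"
    R_sub <- taxon_ratio_matrix(R_sub[, keep_fa, drop = FALSE],
                                provenance = paste0("location ", l))
    S_sub <- sample_matrix(unclass(S)[rows, , drop = FALSE],
                           location = loc[rows])
    res <- runner(S_sub, R_sub, cfg)
    A_all[rows, taxa] <- res$abundances[, taxa]
    per_loc[[l]] <- res
  }
  list(abundances = A_all, per_location = per_loc)
}
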