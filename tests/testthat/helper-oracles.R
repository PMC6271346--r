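# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the simplex optimum is found by exhaustive
# (coarse-to-fine) grid enumeration, ranks are computed by explicit counting,
# and partial correlations by residual regressions.

table3_input <- function() {
  read_ratio_matrix(system.file("extdata", "table3_input.csv",
                                package = "plfatax"))
}

table3_output <- function() {
  read_ratio_matrix(system.file("extdata", "table3_output.csv",
                                package = "plfatax"))
}

# Exhaustive simplex grid search for min RMSE of t(F) %*% a vs s, refined
# down to `res`. The objective is convex in a, so refinement around the
# coarse optimum cannot miss the global optimum by more than one grid step.
grid_simplex_opt <- function(Fmat, s, res = 1e-4) {
  k <- nrow(Fmat)
  stopifnot(k %in% c(2, 3))
  obj_rows <- function(A) {
    E <- A %*% Fmat - matrix(s, nrow(A), length(s), byrow = TRUE)
    sqrt(rowMeans(E^2))
  }
  if (k == 2) {
    a1 <- seq(0, 1, by = res)
    A <- cbind(a1, 1 - a1)
    return(A[which.min(obj_rows(A)), ])
  }
  step <- 0.01
  lo <- c(0, 0)
  hi <- c(1, 1)
  best <- NULL
  repeat {
    g1 <- seq(lo[1], hi[1], by = step)
    g2 <- seq(lo[2], hi[2], by = step)
    G <- expand.grid(a1 = g1, a2 = g2)
    G <- G[G$a1 + G$a2 <= 1 + 1e-12, ]
    A <- cbind(G$a1, G$a2, pmax(0, 1 - G$a1 - G$a2))
    best <- A[which.min(obj_rows(A)), ]
    if (step <= res) break
    step_new <- max(res, step / 10)
    lo <- pmax(0, best[1:2] - 1.5 * step)
    hi <- pmin(1, best[1:2] + 1.5 * step)
    step <- step_new
  }
  best
}

# average ranks by explicit counting (brute force, no rank())
rank_brute <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

# Spearman r from brute-force ranks and the Pearson product-moment formula
spearman_brute <- function(x, y) {
  rx <- rank_brute(x)
  ry <- rank_brute(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# partial correlation of columns i and j controlling all others, via
# regression residuals
partial_cor_lm <- function(x, i, j) {
  others <- x[, -c(i, j), drop = FALSE]
  ri <- stats::residuals(stats::lm(x[, i] ~ others))
  rj <- stats::residuals(stats::lm(x[, j] ~ others))
  stats::cor(ri, rj)
}

# a small weight-percent profile from a named vector (renormalized)
toy_profile <- function(values, id = "toy", fraction = "total", ...) {
  fa_profile(id, values / sum(values) * 100, lipid_fraction = fraction,
             units = "weight_pct", ...)
}
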