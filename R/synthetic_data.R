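# Synthetic pond data: seston PLFA samples mixed from known group
# abundances, cultured-isolate libraries with within-taxon variability, and
# consumer (zooplankton) profiles derived from seston with selective
# retention. Every generated table passes the profiles_io validators, and a
# truth record is kept so closed-loop recovery can be tested.

HETEROTROPH_TAXA <- c("Ascomycetes", "Zygomycetes", "Basidiomycetes",
                      "Actinobacteria", "Firmicutes", "Proteobacteria")
AUTOTROPH_TAXA <- c("Green algae", "Cyanobacteria", "Diatoms")

#' Dirichlet random deviates
#'
#' @param n Number of draws.
#' @param alpha Concentration vector.
#' @return `n` x `length(alpha)` matrix, rows on the unit simplex.
#' @export
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sweep(g, 1, rowSums(g), "/")
}

# multiplicative lognormal factors with unit mean and coefficient of
# variation cv (mean-one keeps generated quantities unbiased around their
# generating values)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Define a synthetic pond scenario
#'
#' @param R_true True taxon ratio matrix generating the seston.
#' @param n_samples Number of seston samples (ponds x dates).
#' @param true_abundances Optional fixed samples x taxa abundance matrix
#'   (rows summing to 1); when `NULL`, abundances are drawn from a Dirichlet
#'   with concentration `dirichlet_alpha`.
#' @param dirichlet_alpha Concentration of the truth Dirichlet (scalar or
#'   one value per taxon; default 1, flat on the simplex).
#' @param noise_model `"lognormal"` (multiplicative, per FA, then
#'   renormalized — the default compositional perturbation) or
#'   `"dirichlet"` (row resampled around the mixed composition).
#' @param cv Coefficient of variation of the lognormal noise (default 0.10).
#' @param dirichlet_concentration Total concentration of the Dirichlet noise
#'   (default 200).
#' @param seed Seed making the scenario reproducible.
#' @param location Optional location label per sample.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(R_true, n_samples = 20,
                               true_abundances = NULL, dirichlet_alpha = 1,
                               noise_model = c("lognormal", "dirichlet"),
                               cv = 0.10, dirichlet_concentration = 200,
                               seed = 1, location = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.matrix(R_true), cv >= 0, n_samples >= 1)
  if (any(rowSums(unclass(R_true)) <= 0))
    stop("degenerate ratio matrix: all-zero taxon", call. = FALSE)
  if (!is.null(true_abundances)) {
    stopifnot(is.matrix(true_abundances),
              ncol(true_abundances) == nrow(R_true))
    if (any(abs(rowSums(true_abundances) - 1) > 1e-9))
      stop("true abundance rows must sum to 1", call. = FALSE)
  }
  structure(list(R_true = R_true, n_samples = as.integer(n_samples),
                 true_abundances = true_abundances,
                 dirichlet_alpha = dirichlet_alpha,
                 noise_model = noise_model, cv = cv,
                 dirichlet_concentration = dirichlet_concentration,
                 seed = as.integer(seed), location = location),
            class = "synthetic_scenario")
}

#' Named scenario presets for the regimes seen in temporary ponds
#'
#' `"heterotroph_dominated"` fixes the summed fungal + bacterial biomass at
#' 0.90 per sample (ponds where heterotrophs dominate the food-web base),
#' `"green_algae_dominated"` fixes green algae at 0.80,
#' `"cyanobacteria_mixed"` fixes cyanobacteria at 0.50, and `"mixed"` draws
#' flat-Dirichlet abundances over all taxa. The remaining mass is split
#' within its group by a Dirichlet draw.
#'
#' @param name Preset name.
#' @param R_true Ratio matrix (default: the packaged input ratio matrix).
#' @param n_samples,seed,cv Passed to [synthetic_scenario()].
#' @return A `synthetic_scenario`.
#' @export
preset_scenario <- function(name = c("mixed", "heterotroph_dominated",
                                     "green_algae_dominated",
                                     "cyanobacteria_mixed"),
                            R_true = NULL, n_samples = 20, seed = 1,
                            cv = 0.10) {
  name <- match.arg(name)
  if (is.null(R_true))
    R_true <- read_ratio_matrix(system.file("extdata", "table3_input.csv",
                                            package = "plfatax"),
                                provenance = "packaged input ratio matrix")
  taxa <- rownames(R_true)
  if (name == "mixed")
    return(synthetic_scenario(R_true, n_samples = n_samples, seed = seed,
                              cv = cv))
  fixed <- switch(name,
    heterotroph_dominated = list(set = intersect(HETEROTROPH_TAXA, taxa),
                                 mass = 0.90),
    green_algae_dominated = list(set = "Green algae", mass = 0.80),
    cyanobacteria_mixed = list(set = "Cyanobacteria", mass = 0.50))
  if (!all(fixed$set %in% taxa))
    stop("preset taxa missing from the ratio matrix", call. = FALSE)
  other <- setdiff(taxa, fixed$set)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  A <- matrix(0, n_samples, length(taxa), dimnames = list(NULL, taxa))
  A[, fixed$set] <- fixed$mass *
    rdirichlet(n_samples, rep(2, length(fixed$set)))
  A[, other] <- (1 - fixed$mass) * rdirichlet(n_samples, rep(2, length(other)))
  synthetic_scenario(R_true, n_samples = n_samples, true_abundances = A,
                     seed = seed, cv = cv)
}

#' Generate seston PLFA samples from a scenario
#'
#' Each sample is the true-abundance mixture of the row-normalized true
#' signatures, perturbed by the scenario's noise model and renormalized to
#' weight percent. The truth record (abundances and generating matrix) is
#' returned for recovery tests.
#'
#' @param sc A [synthetic_scenario()].
#' @return List with `samples` (a [sample_matrix()], weight percent) and
#'   `truth` (list: `abundances`, `R_true`).
#' @export
gen_pond_samples <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(sc$seed)
  R <- unclass(sc$R_true)
  Fmat <- row_norm_signatures(R)
  A <- sc$true_abundances
  if (is.null(A)) {
    alpha <- if (length(sc$dirichlet_alpha) == 1)
      rep(sc$dirichlet_alpha, nrow(R)) else sc$dirichlet_alpha
    A <- rdirichlet(sc$n_samples, alpha)
    colnames(A) <- rownames(R)
  }
  M <- A %*% Fmat
  noisy <- switch(sc$noise_model,
    lognormal = M * matrix(rlnorm_cv(length(M), sc$cv), nrow(M)),
    dirichlet = t(apply(M, 1, function(row)
      rdirichlet(1, row * sc$dirichlet_concentration)[1, ])))
  noisy <- sweep(noisy, 1, rowSums(noisy), "/") * 100
  rownames(noisy) <- sprintf("sample_%02d", seq_len(nrow(noisy)))
  rownames(A) <- rownames(noisy)
  list(samples = sample_matrix(noisy, location = sc$location),
       truth = list(abundances = A, R_true = sc$R_true))
}

#' Generate a cultured-isolate library around taxon mean signatures
#'
#' Each isolate is the taxon's mean ratio vector under multiplicative
#' lognormal within-taxon variation, expressed as a weight-percent profile.
#' [build_ratio_matrix()] on the output recovers the means as the number of
#' isolates grows.
#'
#' @param means A [taxon_ratio_matrix()] of taxon mean signatures.
#' @param cv Within-taxon coefficient of variation (default 0.2).
#' @param n_per_taxon Isolates per taxon.
#' @param seed Seed.
#' @return List of weight-percent `fa_profile` with `meta$taxon` set.
#' @export
gen_isolate_library <- function(means, cv = 0.2, n_per_taxon = 5, seed = 1) {
  stopifnot(is.matrix(means), n_per_taxon >= 1, cv >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  M <- unclass(means)
  out <- list()
  for (tx in rownames(M)) {
    for (i in seq_len(n_per_taxon)) {
      v <- M[tx, ]
      # variation is applied to the ratios (the reference stays put), so the
      # per-taxon mean of normalized isolates is unbiased for the mean ratio
      nz <- v > 0 & names(v) != "16:0"
      v[nz] <- v[nz] * rlnorm_cv(sum(nz), cv)
      out[[length(out) + 1L]] <- fa_profile(
        sprintf("%s_%03d", gsub("\\s+", "_", tx), i),
        v / sum(v) * 100, lipid_fraction = "PLFA",
        units = "weight_pct", meta = list(taxon = tx))
    }
  }
  out
}

#' Define a consumer (zooplankton) generation spec
#'
#' @param retention Named numeric vector of retention factors. Names may be
#'   fatty-acid names (highest precedence), marker group names
#'   (`bacteria`/`fungi`/`autotrophs`), or [classify_fa()] category tags
#'   (multiple matching tag factors multiply). Unmentioned fatty acids have
#'   factor 1.
#' @param de_novo_safa Fraction of consumer FA mass synthesised de novo as
#'   saturates (added as 16:0 and 18:0 in ratio 2:1; default 0).
#' @param phospholipid_pufa_boost Extra multiplicative PUFA retention in the
#'   phospholipid fraction relative to the reserve (neutral) lipids;
#'   must be >= 1 (default 1.5) — membranes conserve PUFA hardest.
#' @param cv Lognormal noise on consumer FA shares (default 0.10).
#' @param fraction_masses Named FA masses of the generated lipid fractions
#'   (stored in `meta$mass`, used when pooling fractions).
#' @return Object of class `consumer_spec`.
#' @export
consumer_spec <- function(retention = c(autotrophs = 1),
                          de_novo_safa = 0, phospholipid_pufa_boost = 1.5,
                          cv = 0.10,
                          fraction_masses = c(neutral = 10,
                                              acetone_mobile = 2,
                                              free_fa = 1,
                                              phospholipid = 4)) {
  stopifnot(all(retention >= 0), de_novo_safa >= 0, de_novo_safa < 1,
            phospholipid_pufa_boost >= 1, cv >= 0)
  structure(list(retention = retention, de_novo_safa = de_novo_safa,
                 phospholipid_pufa_boost = phospholipid_pufa_boost,
                 cv = cv, fraction_masses = fraction_masses),
            class = "consumer_spec")
}

# resolve a retention factor for one fatty acid; retention names that are
# not parseable FA names are treated as group/category keys
resolve_retention <- function(fa_name, retention, scheme) {
  canon <- vapply(names(retention), function(nm)
    tryCatch(parse_fa_name(nm)$name, error = function(e) NA_character_),
    character(1))
  hit <- which(!is.na(canon) & canon == fa_name)
  if (length(hit)) return(unname(retention[hit[1]]))
  f <- 1
  grp <- assign_marker_group(fa_name, scheme)
  if (!is.na(grp) && grp %in% names(retention))
    f <- f * unname(retention[grp])
  tags <- classify_fa(fa_name)
  for (tg in intersect(tags, names(retention)))
    f <- f * unname(retention[tg])
  f
}

#' Generate consumer profiles per lipid fraction from a seston profile
#'
#' Consumer FA shares are proportional to seston share times the retention
#' factor of the FA (renormalized within each fraction), plus an optional de
#' novo saturate fraction; PUFA retention in the phospholipid fraction is
#' boosted relative to the reserve lipids. Each fraction gets an independent
#' noise draw.
#'
#' @param seston Seston `fa_profile` (weight percent).
#' @param spec A [consumer_spec()].
#' @param seed Seed.
#' @param entity_id Identifier for the generated consumer.
#' @param scheme Marker scheme used to resolve group-level retention.
#' @return Named list of weight-percent `fa_profile`, one per lipid fraction
#'   (`neutral`, `acetone_mobile`, `free_fa`, `phospholipid`).
#' @export
gen_consumer_profiles <- function(seston, spec = consumer_spec(), seed = 1,
                                  entity_id = "consumer",
                                  scheme = default_marker_scheme()) {
  stopifnot(inherits(seston, "fa_profile"), inherits(spec, "consumer_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  shares <- seston$values / sum(seston$values)
  fas <- names(shares)
  base_factor <- vapply(fas, resolve_retention, numeric(1),
                        retention = spec$retention, scheme = scheme)
  is_pufa <- vapply(fas, function(nm) "PUFA" %in% classify_fa(nm), logical(1))
  out <- list()
  for (fr in c("neutral", "acetone_mobile", "free_fa", "phospholipid")) {
    f <- base_factor
    if (fr == "phospholipid") f[is_pufa] <- f[is_pufa] * spec$phospholipid_pufa_boost
    w <- shares * f
    if (sum(w) <= 0) stop("all fatty acids suppressed by retention spec",
                          call. = FALSE)
    w <- w / sum(w)
    if (spec$de_novo_safa > 0) {
      w <- w * (1 - spec$de_novo_safa)
      add <- setNames(spec$de_novo_safa * c(2, 1) / 3, c("16:0", "18:0"))
      for (nm in names(add))
        w[nm] <- (if (nm %in% names(w)) w[nm] else 0) + add[nm]
    }
    w <- w * rlnorm_cv(length(w), spec$cv)
    w <- w / sum(w) * 100
    out[[fr]] <- fa_profile(entity_id, w, lipid_fraction = fr,
                            units = "weight_pct",
                            meta = list(mass = unname(
                              spec$fraction_masses[fr])))
  }
  out
}
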