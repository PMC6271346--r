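# Profile I/O, ratio-matrix construction, isolate identification.

test_that("profile tables read back with dialect headers and zero-filled gaps", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("entity_id,lipid_fraction,16:00,18:1w9c",
               "a,PLFA,60,40",
               "b,PLFA,50,50",
               "c,PLFA,100,"), tmp)
  ps <- read_profiles(tmp)
  expect_length(ps, 3)
  expect_named(ps[[1]]$values, c("16:0", "18:1ω9c"))
  expect_equal(unname(ps[[3]]$values), c(100, 0))

  writeLines(c("entity_id,16:0,18:0", "a,120,-20"), tmp)
  expect_error(read_profiles(tmp), "negative")
  writeLines(c("entity_id,16:0,18:0", "a,60,forty"), tmp)
  expect_error(read_profiles(tmp), "malformed")
  writeLines(c("entity_id,16:0,16:00", "a,50,50"), tmp)
  expect_error(read_profiles(tmp), "duplicate")
  writeLines(c("entity_id,18:0,18:1ω9c", "a,50,50"), tmp)
  expect_error(read_profiles(tmp, ratio_source = TRUE), "16:0")
})

test_that("write/read round trip preserves values to full precision", {
  p <- fa_profile("x", c("16:0" = 100 / 3, "18:0" = 100 / 7,
                         "18:1ω9c" = 100 - 100 / 3 - 100 / 7),
                  lipid_fraction = "PLFA", meta = list(taxon = "T"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_profiles(list(p), tmp)
  p2 <- read_profiles(tmp)[[1]]
  expect_identical(p2$values[names(p$values)], p$values)
  expect_identical(p2$meta$taxon, "T")
})

test_that("normalization to 16:0 is idempotent and matches the diatom ratio", {
  v <- c("16:0" = 20, "18:1ω9c" = 10)
  r <- normalize_to_reference(v)
  expect_equal(unname(r), c(1, 0.5))
  expect_equal(normalize_to_reference(r), r)
  # the packaged diatom column carries EPA at 1.76 x the 16:0 mass
  R <- table3_input()
  expect_equal(unclass(R)["Diatoms", "20:5ω3"], 1.76)
  expect_error(normalize_to_reference(c("18:0" = 10)), "absent or zero")
})

test_that("packaged ratio matrices satisfy the 16:0 = 1 reference invariant", {
  for (R in list(table3_input(), table3_output())) {
    expect_s3_class(R, "taxon_ratio_matrix")
    expect_equal(nrow(R), 9)
    expect_identical(unname(unclass(R)[, "16:0"]), rep(1, 9))
  }
  # the four elements the bounded optimization is reported to have adjusted
  Rin <- unclass(table3_input())
  Rout <- unclass(table3_output())
  delta <- which(Rin != Rout, arr.ind = TRUE)
  expect_equal(nrow(delta), 4)
  ratios <- Rout[delta] / Rin[delta]
  expect_true(all(ratios >= 0.5 - 1e-12 & ratios <= 1.5 + 1e-12))
})

test_that("ratio-matrix construction averages, filters and normalizes", {
  mk <- function(id, tx, v) fa_profile(id, v, "PLFA", meta = list(taxon = tx))
  # two identical isolates of one taxon reproduce the profile
  v <- c("16:0" = 40, "18:1ω9c" = 40, "18:0" = 20)
  R <- build_ratio_matrix(list(mk("a1", "A", v), mk("a2", "A", v)),
                          drop_single_species = FALSE)
  expect_equal(unclass(R)["A", c("16:0", "18:1ω9c", "18:0")],
               c("16:0" = 1, "18:1ω9c" = 1, "18:0" = 0.5))

  # an FA present in exactly one taxon is dropped
  iso <- list(
    mk("a1", "A", c("16:0" = 50, "18:0" = 40, "20:5ω3" = 10)),
    mk("b1", "B", c("16:0" = 60, "18:0" = 40)))
  R <- build_ratio_matrix(iso)
  expect_false("20:5ω3" %in% colnames(R))

  # FAs under the mean weight-percent floor in every taxon are dropped
  iso <- list(
    mk("a1", "A", c("16:0" = 59.5, "18:0" = 40, "cy17:0" = 0.5)),
    mk("b1", "B", c("16:0" = 59.2, "18:0" = 40, "cy17:0" = 0.8)))
  R <- build_ratio_matrix(iso)
  expect_false("cy17:0" %in% colnames(R))
  R <- build_ratio_matrix(iso, min_mean_pct = 0.5)
  expect_true("cy17:0" %in% colnames(R))

  # a taxon reduced to 16:0 alone is an error
  iso <- list(mk("a1", "A", c("16:0" = 99.5, "cy17:0" = 0.5)),
              mk("b1", "B", c("16:0" = 50, "18:0" = 50)))
  expect_error(build_ratio_matrix(iso), "no surviving")
})

test_that("taxon means are recovered exactly from a mixed synthetic library", {
  set.seed(7)
  fas <- c("16:0", "18:0", "18:1ω9c", "20:5ω3", "a-15:0")
  taxa <- c("A", "B", "C")
  profs <- list()
  for (tx in taxa) for (i in 1:5) {
    v <- setNames(runif(5, 5, 40), fas)
    profs[[length(profs) + 1]] <-
      fa_profile(paste0(tx, i), v / sum(v) * 100, "PLFA",
                 meta = list(taxon = tx))
  }
  R <- build_ratio_matrix(profs, min_mean_pct = 0,
                          drop_single_species = FALSE)
  # oracle: direct per-taxon averaging of 16:0-normalized vectors
  for (tx in taxa) {
    rows <- profs[vapply(profs, function(p) p$meta$taxon == tx, logical(1))]
    manual <- rowMeans(vapply(rows, function(p)
      p$values[fas] / p$values[["16:0"]], numeric(5)))
    expect_equal(unclass(R)[tx, fas], manual, tolerance = 1e-12)
  }
  # ratios are invariant to per-isolate scaling
  profs_scaled <- lapply(profs, function(p)
    fa_profile(p$entity_id, p$values * 3, "PLFA", units = "mass",
               meta = p$meta))
  R2 <- build_ratio_matrix(profs_scaled, min_mean_pct = 0,
                           drop_single_species = FALSE)
  expect_equal(unclass(R2), unclass(R), tolerance = 1e-12)
})

test_that("library identification is exact, tie-stable and noise-robust", {
  mk <- function(id, tx, v) fa_profile(id, v, "PLFA", meta = list(taxon = tx))
  lib <- reference_library(list(
    mk("b", "Btax", c("16:0" = 52, "18:0" = 48)),
    mk("a", "Atax", c("16:0" = 48, "18:0" = 52))))
  q <- fa_profile("q", c("16:0" = 50, "18:0" = 50), "PLFA")
  hits <- identify_isolate(q, lib, top_k = 2)
  expect_equal(hits$taxon, c("Atax", "Btax"))  # equidistant: label order
  expect_equal(hits$score[1], hits$score[2])

  hits <- identify_isolate(mk("x", "Atax", c("16:0" = 48, "18:0" = 52)), lib)
  expect_equal(hits$taxon[1], "Atax")
  expect_equal(hits$score[1], 1)

  # 20-entry random library; queries = entry + 2% multiplicative noise
  set.seed(11)
  fas <- canonicalize_fa_names(
    c("16:0", "18:0", "18:1ω9c", "18:2ω6c", "20:5ω3", "a-15:0", "cy17:0"))
  entries <- lapply(1:20, function(i) {
    v <- setNames(runif(7, 1, 30), fas)
    mk(paste0("e", i), sprintf("tax%02d", i), v / sum(v) * 100)
  })
  lib <- reference_library(entries)
  correct <- 0
  for (trial in 1:200) {
    i <- sample(20, 1)
    v <- entries[[i]]$values * exp(rnorm(7, 0, 0.02))
    q <- fa_profile("q", v / sum(v) * 100, "PLFA")
    if (identify_isolate(q, lib, 1)$taxon == sprintf("tax%02d", i))
      correct <- correct + 1
  }
  expect_gte(correct / 200, 0.95)
  expect_error(identify_isolate(q, reference_library(entries[0]), 1))
})
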