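#!/usr/bin/env Rscript
# Build a taxon x PLFA ratio matrix from a cultured-isolate library and check
# that library identification and ratio reconstruction behave.
#
# Field isolates are not deposited, so the library is simulated around the
# packaged taxon signatures (9 taxa: 3 fungal phyla, 3 bacterial phyla,
# 3 algal groups) with 20% within-taxon variation — about what repeated
# cultures of one genus show.

suppressPackageStartupMessages(library(plfatax))
dir.create("results", showWarnings = FALSE)
seed <- 1

R_ref <- read_ratio_matrix(system.file("extdata", "table3_input.csv",
                                       package = "plfatax"))

isolates <- gen_isolate_library(R_ref, cv = 0.2, n_per_taxon = 25,
                                seed = seed)
write_profiles(isolates, "results/isolate_library.csv")

R_hat <- build_ratio_matrix(isolates, min_mean_pct = 0,
                            drop_single_species = FALSE,
                            provenance = "rebuilt from 225 synthetic isolates")
write_ratio_matrix(R_hat, "results/ratio_matrix_rebuilt.csv")

nz <- unclass(R_ref) > 0
rel_err <- abs(unclass(R_hat)[, colnames(R_ref)][nz] / unclass(R_ref)[nz] - 1)
cat(sprintf("ratio recovery from 25 isolates/taxon: median |rel err| %.3f, max %.3f\n",
            median(rel_err), max(rel_err)))

# held-out isolates identified against the library
lib <- reference_library(isolates)
held_out <- gen_isolate_library(R_ref, cv = 0.2, n_per_taxon = 10, seed = 99)
top1 <- vapply(held_out, function(q)
  identify_isolate(q, lib, 1)$taxon == q$meta$taxon, logical(1))
cat(sprintf("held-out identification: %.0f%% top-1 correct (%d queries)\n",
            100 * mean(top1), length(top1)))
write.csv(data.frame(query = vapply(held_out, `[[`, "", "entity_id"),
                     truth = vapply(held_out, function(q) q$meta$taxon, ""),
                     top1_correct = top1),
          "results/identification_heldout.csv", row.names = FALSE)
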