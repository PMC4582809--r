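#!/usr/bin/env Rscript
# Stage 3: build a maximum-probability ROI atlas from simulated rater
# drawings, generate a synthetic 8-patient lesion cohort, quantify per-ROI
# damage, and verify the measured damage equals the generator's ground truth.

library(semconf)

dir.create("results", showWarnings = FALSE)
cfg <- cohort_gen_config(seed = 21L)
co <- gen_lesion_cohort(cfg)

# multi-rater atlas demonstration: jitter each ROI box across 3 raters
set.seed(21)
drawings <- lapply(cfg$roi_layout, function(box) {
  lapply(1:3, function(r) {
    jit <- sample(-1:1, 1)
    b <- box
    b$y <- pmax(1, pmin(cfg$grid_dim[2], b$y + jit))
    a <- array(0, cfg$grid_dim)
    a[as.matrix(expand.grid(b$x, b$y, b$z))] <- 1
    binary_mask(a, voxel_dims = cfg$voxel_dims)
  })
})
mp <- build_max_prob_atlas(drawings)
tied <- sum(mp$atlas$labels == 0 &
              Reduce(`+`, lapply(mp$prob_maps, `[[`, "data")) > 0)
message("Max-probability atlas built from 3 raters per ROI; ",
        tied, " voxels left undefined by ties.")
atl <- truncate_posterior(mp$atlas, c("Fusiform", "ITG", "MTG"), "PRc")

profiles <- Map(function(m, id) roi_damage_profile(m, co$atlas, id),
                co$masks, names(co$masks))
dm <- damage_matrix(unname(profiles))
stopifnot(all(abs(dm - damage_matrix(unname(co$profiles))) < 1e-12))
message("Measured damage equals generator ground truth for all ",
        nrow(dm), " patients x ", ncol(dm), " ROIs.")
write.table(data.frame(patient = rownames(dm), dm),
            "results/damage_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ic <- damage_intercorrelations(unname(profiles))
write.table(data.frame(roi = rownames(ic$r), round(ic$r, 3)),
            "results/damage_intercorrelations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PRc-Fusiform damage correlation: r = %.2f (p = %.2f)",
                ic$r["PRc", "Fusiform"], ic$p["PRc", "Fusiform"]))
vols <- sapply(profiles, function(p) p$lesion_volume_cm3)
message(sprintf("Cohort lesion volumes: %.1f-%.1f cm3",
                min(vols), max(vols)))
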