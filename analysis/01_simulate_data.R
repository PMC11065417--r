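#!/usr/bin/env Rscript
# Step 1: simulate the study populations.
# Generates the in-distribution feature population (10 classes, 16-D,
# class-conditional Gaussian), OOD sets at a near and a far shift, and a
# small toy image dataset for the image-level path. Everything is a pure
# function of the seed; tables land under results/data/.

library(oodeval)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- feature_space_spec(n_classes = 10, dim = 16, mean_scale = 3,
                           within_cov = 1, seed = seed)
profile <- make_class_size_profile("balanced", n_total = 1000,
                                   n_classes = 10)
id <- generate_id_features(spec, profile)
write_feature_table(id, file.path(out, "id_features.csv"))

ood_near <- generate_ood_features(spec, ood_shift_spec(4, 500))
ood_far <- generate_ood_features(spec, ood_shift_spec(20, 500),
                                 seed = seed + 100L)
write_feature_table(ood_near, file.path(out, "ood_near_delta4.csv"))
write_feature_table(ood_far, file.path(out, "ood_far_delta20.csv"))

man <- generate_toy_images(file.path(out, "toy_images"), n_classes = 4,
                           per_class_counts = 50, ood_count = 25,
                           seed = seed)

cat("ID samples:        ", nrow(id), " (",
    paste(range(table(id$label)), collapse = "-"),
    " per class)\n", sep = "")
cat("OOD samples:       ", nrow(ood_near), " near (delta=4), ",
    nrow(ood_far), " far (delta=20)\n", sep = "")
cat("Toy images:        ", sum(man$domain == "ID"), " ID + ",
    sum(man$domain == "OOD"), " OOD PNGs under ",
    file.path(out, "toy_images"), "\n", sep = "")
cat("Finding: ID classes are well separated (mean cloud scale 3 vs unit",
    "within-class SD); the near-OOD set overlaps the ID cloud, the far",
    "set does not.\n")
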