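#!/usr/bin/env Rscript
# Stage 4: wing geometric morphometrics.
#
# Reads the simulated forewing landmarks (20 landmarks per specimen, with
# image-scale calibration), computes centroid sizes, runs one-way ANOVA with
# LSD letters across regions, aligns all specimens by Generalized Procrustes
# Analysis, summarises shape variation by PCA, and regresses per-site mean
# centroid size on latitude/longitude/altitude by p-value stepwise selection.

suppressPackageStartupMessages(library(apiscan))

fx <- "results/fixture"
out <- "results/morpho"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- list(stage = "morpho", alpha = 0.05, alpha_enter = 0.05,
               alpha_remove = 0.10, gpa_tol = 1e-8,
               forewing_baseline = c(1, 7))

cfgs <- read_tps(file.path(fx, "forewing.tps"))
meta <- read.delim(file.path(fx, "wing_metadata.tsv"))
meta <- meta[match(vapply(cfgs, `[[`, "", "id"), meta$specimen), ]

cs <- vapply(cfgs, function(c) centroid_size(c$coords), 0)
cs_tab <- data.frame(specimen = meta$specimen, region = meta$group,
                     site = meta$site, cs = cs)
write.table(cs_tab, file.path(out, "centroid_size.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

an <- anova_lsd(cs, meta$group, alpha = params$alpha)
cat(sprintf("CS one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
            an$df_between, an$df_within, an$F, an$p_value))
letters_tab <- merge(an$means,
                     data.frame(group = names(an$letters),
                                letters = unname(an$letters)))
print(letters_tab)
write.table(an$lsd, file.path(out, "lsd_pairwise.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(letters_tab, file.path(out, "cs_group_letters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

res <- gpa_align(cfgs, tol = params$gpa_tol)
cat("GPA converged in", res$iterations, "iterations; residual SS =",
    format(tail(res$objective, 1), digits = 4), "\n")
aligned_cfgs <- lapply(seq_along(cfgs), function(i)
  list(id = cfgs[[i]]$id, coords = res$aligned[i, , ], scale = NULL))
write_tps(aligned_cfgs, file.path(out, "aligned.tps"))

pc <- shape_pca(res)
cat(sprintf("Shape PC1+PC2 explain %.2f%% of variance\n",
            100 * sum(pc$explained[1:2])))
write.table(cbind(specimen = meta$specimen, region = meta$group,
                  as.data.frame(pc$scores[, 1:5])),
            file.path(out, "shape_pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

site_means <- aggregate(cbind(cs, latitude, longitude, altitude) ~ site,
                        data = cbind(cs_tab, meta[c("latitude", "longitude",
                                                    "altitude")]),
                        FUN = mean)
st <- suppressWarnings(stepwise_cs_regression(
  site_means, alpha_enter = params$alpha_enter,
  alpha_remove = params$alpha_remove))
cat("Stepwise CS-on-geography model:",
    if (length(st$terms)) paste(st$terms, collapse = " + ") else "(empty)",
    "\n")
print(summary(st$model)$coefficients)
write.table(data.frame(term = names(st$coefficients),
                       coefficient = unname(st$coefficients)),
            file.path(out, "cs_geography_model.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(params, file.path(out, "params.json"),
                     auto_unbox = TRUE, pretty = TRUE)
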