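#!/usr/bin/env Rscript
# Chemometric screening of the matched 18 x 18 peak table: PCA to see
# whether the two production regions separate, OPLS-DA with one
# orthogonal component to model the separation, a 200-permutation test
# of model validity, and marker selection by VIP > 1 with Welch p <
# 0.05. Writes scores, S-plot coordinates, the marker report, and (if
# ggplot2 is available) score/permutation plots.

library(herbqc)
seed <- 0
ptable <- read_peak_table("results/peak_table_matched.csv")
X <- preprocess(ptable, "autoscale")

pca <- pca_fit(X, n_components = 4)
cat(sprintf("PCA: four components explain R2X(cum) = %.3f\n", pca$R2X_cum))
write.csv(data.frame(batch = rownames(pca$scores),
                     region = ptable$regions, pca$scores),
          "results/pca_scores.csv", row.names = FALSE)

opls <- oplsda(X, ptable$regions, n_orthogonal = 1)
cat(sprintf("OPLS-DA: R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
            opls$R2X_cum, opls$R2Y, opls$Q2))

perm <- permutation_test(X, ptable$regions, n_perm = 200, seed = seed)
cat(sprintf("permutation test (200 label shuffles): all permuted Q2 < original: %s\n",
            all(perm$permutations$Q2 < perm$original$Q2)))
cat(sprintf("  intercepts: R2 = %.3f, Q2 = %.3f\n",
            perm$r2_intercept, perm$q2_intercept))
write.csv(perm$permutations, "results/permutations.csv", row.names = FALSE)

sp <- s_plot(opls, X)
write.csv(sp, "results/s_plot.csv", row.names = FALSE)

markers <- select_markers(ptable, opls)
write.csv(markers, "results/markers.csv", row.names = FALSE)
sel <- markers$peak_id[markers$selected]
info <- default_peak_info()
cat(sprintf("selected markers (VIP > 1 and p < 0.05): peaks %s\n",
            paste(sort(as.integer(sel)), collapse = ", ")))
cat(paste0("  ", sel, " = ",
           info$compound[match(sel, info$peak_id)], collapse = "\n"), "\n")

# plots (ggplot2 is not attached: it masks annotate()/resolution())
if (requireNamespace("ggplot2", quietly = TRUE)) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  dir.create("results/figures", showWarnings = FALSE)
  sc <- data.frame(batch = rownames(pca$scores), region = ptable$regions,
                   pca$scores)
  ggplot2::ggsave("results/figures/pca_scores.pdf", width = 5, height = 4,
                  plot = gg(sc, aes(PC1, PC2, colour = region)) +
                    ggplot2::geom_point(size = 2) + ggplot2::theme_bw() +
                    ggplot2::labs(title = "PCA of the common-peak matrix"))
  pp <- rbind(perm$permutations,
              data.frame(correlation = 1, R2Y = perm$original$R2Y,
                         Q2 = perm$original$Q2))
  ggplot2::ggsave("results/figures/permutation.pdf", width = 5, height = 4,
                  plot = gg(pp, aes(correlation)) +
                    ggplot2::geom_point(aes(y = R2Y), colour = "steelblue") +
                    ggplot2::geom_point(aes(y = Q2), colour = "firebrick") +
                    ggplot2::theme_bw() +
                    ggplot2::labs(y = "R2Y (blue) / Q2 (red)",
                                  x = "|correlation| with original labels",
                                  title = "200-permutation validation"))
  cat("wrote score and permutation plots under results/figures/\n")
}
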