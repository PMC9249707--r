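#!/usr/bin/env Rscript
# Step 3 — observer-study statistics.
#
# Part A recomputes the per-rater and pooled diagnostic table from the
# seven raters' printed inhomogeneity counts over the 60 sequences
# (27 benign / 33 SCC): sensitivity and specificity with Wilson 95% CIs in
# the study's truncation display convention, and each rater's chi-square.
# All values are recomputed from counts, so rows whose published display
# percentages carry typos come out at the count-derived values.
#
# Part B asks whether the published inter-rater agreement (Fleiss kappa
# 0.53, "moderate") is consistent with raters behaving as independent
# Bernoulli raters at their observed operating points: the item-level
# rating matrix behind the published kappa was never released, so this is a
# distributional plausibility check, not a reproduction.

library(clehom)

dir.create("results", showWarnings = FALSE)

## A: diagnostic table from counts
tab <- rater_table(cle_observer_counts())
write.csv(tab, file.path("results", "rater_table.csv"), row.names = FALSE)
all_row <- tab[tab$rater == "All", ]
cat(sprintf("pooled: sensitivity %.1f%% (%.1f-%.1f), specificity %.1f%% (%.1f-%.1f)\n",
            all_row$sensitivity_pct,
            percent_trunc(all_row$sens_lower), percent_trunc(all_row$sens_upper),
            all_row$specificity_pct,
            percent_trunc(all_row$spec_lower), percent_trunc(all_row$spec_upper)))
pooled_chi <- chi_square_2x2(matrix(c(189, 26, 42, 163), 2))
cat(sprintf("pooled chi-square: X2 = %.1f, p = %.3g\n",
            pooled_chi$statistic, pooled_chi$p))

## B: kappa plausibility under independent Bernoulli raters
set.seed(108)
labels <- rep(c("benign", "scc"), times = c(27, 33))
profiles <- observer_rater_profiles()
kappas <- replicate(400, fleiss_kappa(simulate_raters(labels, profiles))$kappa)
qs <- quantile(kappas, c(0.025, 0.5, 0.975))
write.csv(data.frame(replicate = seq_along(kappas), kappa = kappas),
          file.path("results", "kappa_simulation.csv"), row.names = FALSE)
cat(sprintf("simulated panel kappa: median %.3f (central 95%%: %.3f-%.3f), band %s\n",
            qs[[2]], qs[[1]], qs[[3]], interpret_kappa(qs[[2]])))
cat(sprintf("published kappa 0.53 %s the central interval\n",
            if (qs[[1]] < 0.53 && 0.53 < qs[[3]]) "lies inside" else "falls outside"))
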