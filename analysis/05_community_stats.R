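#!/usr/bin/env Rscript
# Stage 5: comparative statistics.
#
# On the final transfer: Bray-Curtis PERMANOVA by initial evenness class
# (999 permutations), PCoA, and pairwise dispersion contrasts. Across
# transfers: the permutation trend test of phenotypic D2 per evenness
# group. Globally: MFA of species relative abundances and diversity
# indices with the evenness class as categorical block, and the
# phenotypic-taxonomic diversity correlation at the final transfer.

library(evenpanel)

seed <- 777L
counts <- read_count_tsv("results/amplicon_counts.tsv")
div <- read.table("results/taxonomic_diversity.tsv", sep = "\t",
                  header = TRUE)
fcm <- read.table("results/fcm_diversity.tsv", sep = "\t", header = TRUE)

filtered <- filter_phylotypes(counts)
rare <- rarefy_counts(filtered, depth = 3317,
                      seed = derive_seed(seed, "rarefy"))

final <- div[div$transfer == 5, ]
d_bc <- bray_curtis(rare[, final$sample_id])

perm <- permanova(d_bc, final$evenness_class, n_perm = 999,
                  seed = derive_seed(seed, "permanova"))
cat(sprintf("PERMANOVA (evenness, transfer 5): R2 = %.5f, P = %.3f\n",
            perm$r_squared, perm$p_value))

ord <- pcoa_ordination(d_bc, k = 4)
coords <- data.frame(sample_id = final$sample_id,
                     evenness_class = final$evenness_class,
                     ord$coordinates)
write.table(coords, "results/pcoa_coordinates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("PCoA variance share:", round(100 * ord$proportion, 1), "%\n")

disp <- group_dispersion(d_bc, final$evenness_class, n_perm = 999,
                         seed = derive_seed(seed, "disp"))
write.table(disp$pairwise, "results/dispersion_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# trend of phenotypic D2 across transfers, per evenness group
trend_rows <- list()
for (cl in c("Low", "Medium", "High")) {
  sub <- fcm[fcm$evenness_class == cl, ]
  wide <- stats::reshape(sub[c("community_id", "transfer", "D2")],
                         idvar = "community_id", timevar = "transfer",
                         direction = "wide")
  v <- as.matrix(wide[, -1])
  tt <- diversity_trend_test(v, n_perm = 999,
                             seed = derive_seed(seed, "trend", cl))
  trend_rows[[cl]] <- data.frame(
    evenness_class = cl, mean_slope = tt$mean_slope,
    p_value = tt$p_value, n_perm = tt$n_permutations)
  cat(sprintf("D2 trend %s: mean slope %.2f per transfer, P = %.3f\n",
              cl, tt$mean_slope, tt$p_value))
}
write.table(do.call(rbind, trend_rows), "results/trend_tests.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# MFA: species relative abundances + diversity indices, evenness active
rel <- t(sweep(rare[, final$sample_id], 2,
               colSums(rare[, final$sample_id]), "/"))
idx <- final[c("richness", "shannon", "pielou", "simpson", "inv_simpson",
               "fisher_alpha")]
idx$pielou[is.na(idx$pielou)] <- 0
idx$fisher_alpha[is.na(idx$fisher_alpha)] <- 0
m <- mfa(list(abundance = rel, diversity = as.matrix(idx)),
         categorical = final$evenness_class)
cat("MFA dimension variance (%):", round(m$variance_pct, 1), "\n")
cat("v-tests (evenness classes x dimensions):\n")
print(round(m$v_tests, 2))
write.table(data.frame(category = rownames(m$v_tests),
                       round(m$v_tests, 4)),
            "results/mfa_vtests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

# phenotypic vs taxonomic D2 at the final transfer
fcm5 <- fcm[fcm$transfer == 5, ]
ph <- stats::setNames(fcm5$D2, fcm5$community_id)
tx <- stats::setNames(final$D2, final$community_id)
rc <- pheno_taxo_correlation(ph, tx, n_boot = 999,
                             seed = derive_seed(seed, "cor"))
cat(sprintf("pheno vs taxo D2 (transfer 5): Pearson %.3f [%.3f, %.3f], Spearman %.3f\n",
            rc$pearson["estimate"], rc$pearson["ci_lower"],
            rc$pearson["ci_upper"], rc$spearman["estimate"]))
saveRDS <- NULL  # (no binary outputs from analysis stages)
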