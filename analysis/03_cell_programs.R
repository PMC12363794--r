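#!/usr/bin/env Rscript
# Stage 3: single-cell program scoring, subtype and MR-TF module
# assignment, pseudotime smoothing, differential expression under EZH2
# inhibition, permutation GSEA, and the integration of differential
# expression with the chromatin transition classes from stage 2.

library(plastichrom)

dir.create("results/programs", showWarnings = FALSE, recursive = TRUE)
counts <- read_counts_mtx("results/data")
meta <- read_tsv("results/data/cellmeta.tsv")
sets <- read_gmt("results/data/programs.gmt")

norm <- normalize_log(counts)
meta <- meta[match(colnames(norm), meta$cell_id), ]
scores <- score_signatures(norm, sets)
write_tsv(data.frame(cell_id = rownames(scores), scores, check.names = FALSE),
          "results/programs/scores.tsv")

## Cluster-level subtype assignment (clusters are labelled, not cells)
sub <- assign_subtype(scores, level = "cluster", clusters = meta$cluster)
write_tsv(sub, "results/programs/subtypes.tsv")
cat("Cluster-level subtype calls:\n")
print(unique(sub[, c("cluster", "subtype", "margin")]))

## MR-TF modules: the vehicle-dominant cluster's program stands in for the
## NEPC-associated TF group, the others for transition- and
## adenocarcinoma-associated groups
tf_sets <- list(NEPC_TFs = sets$program_cluster1,
                transition_TFs = sets$program_cluster3,
                adeno_TFs = sets$program_cluster5)
tf_scores <- score_signatures(norm, tf_sets)
mods <- mrtf_modules(tf_scores, pseudotime = meta$pseudotime,
                     subtype = sub$subtype)
write_tsv(mods, "results/programs/modules.tsv")
cat("\nModule summary (0 = NEPC, 1 = transition, 2 = adenocarcinoma):\n")
print(attr(mods, "module_summary"))
veh0 <- mean(mods$module[meta$treatment == "vehicle"] == 0)
ezh0 <- mean(mods$module[meta$treatment == "EZH2i"] == 0)
cat(sprintf("module-0 fraction: vehicle %.2f vs EZH2i %.2f\n", veh0, ezh0))

## Program trajectories along pseudotime
prof <- do.call(rbind, lapply(colnames(scores), function(nm) {
  pr <- pseudotime_profile(scores[, nm], meta$pseudotime, df = 5)
  data.frame(set = nm, pseudotime = pr$grid, fitted = pr$fitted,
             residual_sd = pr$residual_sd)
}))
write_tsv(prof, "results/programs/profiles.tsv", params = list(df = 5))

## Differential expression: EZH2i vs vehicle, then pre-ranked GSEA
de <- de_rank(norm, meta$cell_id[meta$treatment == "EZH2i"],
              meta$cell_id[meta$treatment == "vehicle"])
names(de)[names(de) == "lfc"] <- "effect"
write_tsv(de, "results/programs/de.tsv")
gsea <- gsea_preranked(setNames(de$stat, de$gene_id), sets,
                       n_perm = 1000, seed = 1)
write_tsv(gsea, "results/programs/gsea.tsv",
          params = list(n_perm = 1000, seed = 1))
cat("\nTop GSEA hits (EZH2i vs vehicle):\n")
print(head(gsea[, c("set", "size", "es", "nes", "p", "q")], 5))

## Which chromatin transition classes are most targeted by EZH2 inhibition
states <- read_tsv("results/chromstate/states.tsv")
tt <- transition_matrix(states[states$condition == "cond1", ],
                        states[states$condition == "cond2", ])
enr <- integrate_with_de(tt, de, direction = "up", q_max = 0.05)
write_tsv(enr, "results/programs/state_enrichment.tsv",
          params = list(direction = "up", q_max = 0.05))
cat("\nTransition classes ranked by up-regulation enrichment:\n")
print(head(enr[enr$level == "cond2_state", ], 4))
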