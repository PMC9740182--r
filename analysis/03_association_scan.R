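#!/usr/bin/env Rscript
# Feature-wide association scan: batch-correct and z-score the feature table,
# fit one sex- and age-adjusted logistic model per feature, control FDR by
# Benjamini-Hochberg, and summarise effects per elemental pathway.
# Writes association.csv and pathway_summary.csv under results/.

suppressMessages(library(hairdyn))

cohort <- read_cohort(file.path("results", "cohort", "manifest.json"))
feats <- read.csv(file.path("results", "features.csv"), check.names = FALSE)
rownames(feats) <- feats$subject_id
feats$subject_id <- NULL
prov <- read.csv(file.path("results", "feature_provenance.csv"))
attr(feats, "provenance") <- prov

batch <- cohort$subjects$batch[match(rownames(feats),
                                     cohort$subjects$subject_id)]
norm <- batch_correct_and_zscore(feats, batch)
rows <- associate(norm, cohort$subjects, fdr_alpha = 0.05)
write.csv(rows, file.path("results", "association.csv"), row.names = FALSE)

fs <- forest_summary(rows)
write.csv(fs$summary, file.path("results", "pathway_summary.csv"),
          row.names = FALSE)

message(sum(rows$significant), " of ", nrow(rows),
        " features significant at FDR < 0.05")
message("per-pathway counts (top rows):")
print(head(fs$summary, 8))
sig <- rows[rows$significant & !is.na(rows$beta), ]
message("sign split among significant features: ",
        sum(sig$beta > 0), " positive / ", sum(sig$beta < 0), " negative")
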