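#!/usr/bin/env Rscript
# Diagnostic classifier: 80/20 random split, training-set-only feature
# screening, gradient-boosting hyperparameters tuned by surrogate-assisted
# search under 5-fold cross-validation, holdout evaluation at the
# Youden-optimal ROC threshold, and sex-stratified AUC comparisons.
# Writes model_report.json, roc.csv and strata.csv under results/.

suppressMessages(library(hairdyn))

cohort <- read_cohort(file.path("results", "cohort", "manifest.json"))
feats <- read.csv(file.path("results", "features.csv"), check.names = FALSE)
rownames(feats) <- feats$subject_id
feats$subject_id <- NULL
attr(feats, "provenance") <-
  read.csv(file.path("results", "feature_provenance.csv"))

batch <- cohort$subjects$batch[match(rownames(feats),
                                     cohort$subjects$subject_id)]
norm <- batch_correct_and_zscore(feats, batch)
ids <- rownames(norm)
labels <- cohort$subjects$diagnosis[match(ids, cohort$subjects$subject_id)]

sp <- split_subjects(ids, labels, train_fraction = 0.8, seed = 20260102)
message("split: ", length(sp$train_ids), " train (", sp$train_cases,
        " cases) / ", length(sp$holdout_ids), " holdout (",
        sp$holdout_cases, " cases)")

tr <- norm[sp$train_ids, , drop = FALSE]
ho <- norm[sp$holdout_ids, , drop = FALSE]
ho_hash <- data_fingerprint(ho)

sel <- screen_features(tr, cohort$subjects, k = 64)
y_tr <- as.integer(labels[match(sp$train_ids, ids)] == "case")
model <- tune_and_fit(as.matrix(tr[, sel]), y_tr, folds = 5, budget = 15,
                      seed = 20260103)
message(sprintf("tuned booster: CV AUC %.3f (eta %.3g, depth %d, %d rounds)",
                model$best_cv_auc, model$best_params$eta,
                model$best_params$max_depth, model$nrounds))

stopifnot(identical(ho_hash, data_fingerprint(ho)))  # leakage guard
scores <- predict_scores(model, as.matrix(ho[, sel]))
y_ho <- labels[match(sp$holdout_ids, ids)]
report <- evaluate_scores(scores, y_ho)
print(report)

strata <- stratified_performance(
  scores, y_ho,
  cohort$subjects$sex[match(sp$holdout_ids, cohort$subjects$subject_id)])
print(strata)

write.csv(report$roc, file.path("results", "roc.csv"), row.names = FALSE)
write.csv(strata, file.path("results", "strata.csv"), row.names = FALSE)
jsonlite::write_json(
  list(auc = report$auc, youden_threshold = report$youden_threshold,
       j = report$j, confusion = as.list(report$confusion$counts),
       sensitivity = report$confusion$sensitivity,
       specificity = report$confusion$specificity,
       accuracy = report$confusion$accuracy,
       screened_features = sel, best_params = as.list(model$best_params)),
  file.path("results", "model_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
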