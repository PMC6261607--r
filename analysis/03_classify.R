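#!/usr/bin/env Rscript
## Step 3 -- control-anchored classification and assay quality.
##
## Trains the linear SVM on the control-well cells from step 2, reports
## stratified 10-fold CV accuracy, ranks the feature weights, aggregates
## per-cell labels to per-well percent effect and computes the Z' factor
## of the screening window.

suppressMessages(library(myoscreen))
seed <- 1L
layout <- generate_plate_layout(16, 24, hca_design())
features <- read_plate_csv("results/cell_features.csv")

model <- train_classifier(features, layout, k = 10,
                          seed = derive_seed(seed, "svm"))
cat(sprintf("10-fold CV accuracy: %.1f%% (%d training cells)\n",
            100 * model$cv_accuracy, model$n_train))
save_classifier(model, "results/classifier_model.json")

weights <- rank_feature_weights(model)
write.csv(weights, "results/feature_weights.csv", row.names = FALSE)
cat("top 5 features by |weight|:\n")
print(head(weights[, c("rank", "feature", "weight")], 5), row.names = FALSE)

labels <- classify_cells(model, features)
eff <- well_percent_effect(labels, layout)
write.csv(eff, "results/well_effects.csv", row.names = FALSE)

z <- zprime(eff$percent_effect[eff$role == "pos_control"],
            eff$percent_effect[eff$role == "neg_control"])
cat(sprintf("controls: neg %.1f%% (SD %.1f), pos %.1f%% (SD %.1f)\n",
            z$mu_neg, z$sigma_neg, z$mu_pos, z$sigma_pos))
cat(sprintf("Z' = %.2f\n", z$zprime))
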