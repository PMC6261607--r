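## Shared fixtures, built once per test run and cached (image-based plates
## are the expensive part of the suite).
.fixtures <- new.env(parent = emptyenv())

## small two-class feature table with wells mapped to control roles
toy_feature_plate <- function(n_per_class = 100, delta = 3, sdev = 1,
                              p = 4, seed = 1, n_wells = 4) {
  set.seed(seed)
  mk <- function(mu, wells) {
    X <- matrix(rnorm(n_per_class * p, mu, sdev), n_per_class, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    data.frame(well = rep_len(wells, n_per_class),
               cell_id = seq_len(n_per_class), X,
               stringsAsFactors = FALSE)
  }
  neg_wells <- sprintf("N%02d", seq_len(n_wells))
  pos_wells <- sprintf("P%02d", seq_len(n_wells))
  features <- rbind(mk(delta, neg_wells), mk(-delta, pos_wells))
  layout <- data.frame(
    well = c(neg_wells, pos_wells),
    role = rep(c("neg_control", "pos_control"), each = n_wells),
    stringsAsFactors = FALSE)
  list(features = features, layout = layout,
       truth = rep(c("myofibroblast", "fibroblast"), each = n_per_class))
}

## mid-size imaged control plate for the classifier unit tests
small_control_plate <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  design <- list(neg_cols = 1, pos_cols = 8, baseline_cols = integer(),
                 tgf_dose = 5)
  layout <- generate_plate_layout(8, 8, design)  # 8 wells per control role
  sim <- simulate_hca_controls(layout, cells_per_well = 25, seed = 202,
                               dim = c(224, 224))
  .fixtures$small <- c(sim, list(layout = layout))
  .fixtures$small
}

## full-size plate for the acceptance checks: 32 control wells per role,
## >= 500 cells per class
acceptance_plate <- function() {
  if (!is.null(.fixtures$accept)) return(.fixtures$accept)
  layout <- generate_plate_layout(16, 24, hca_design())
  sim <- simulate_hca_controls(layout, cells_per_well = 20, seed = 101,
                               dim = c(224, 224))
  model <- train_classifier(sim$features, layout, k = 10, seed = 101)
  .fixtures$accept <- list(sim = sim, layout = layout, model = model)
  .fixtures$accept
}
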