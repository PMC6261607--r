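#!/usr/bin/env Rscript
## Step 1 -- generate the synthetic study materials.
##
## Builds the 384-well high-content plate layout, a 96-well impedance/MS
## plate, a 1585-compound screening registry with ground truth, and one
## example imaged well, and writes the plain-text artifacts under
## results/.  Everything downstream re-derives what it needs from the
## same seeds, so this step is documentation as much as data generation.

suppressMessages(library(myoscreen))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 1L

hca <- generate_plate_layout(16, 24, hca_design())
write_plate_csv(hca, "results/plate_map_hca.csv")
ipqa <- generate_plate_layout(8, 12, ipqa_design())
write_plate_csv(ipqa, "results/plate_map_ipqa.csv")
cat("HCA plate:", nrow(hca), "wells;",
    sum(hca$role == "neg_control"), "neg /",
    sum(hca$role == "pos_control"), "pos controls\n")

## the screening library: 1585 entries as screened, ~10% true actives
registry <- generate_compound_library(1585, frac_active = 0.1,
                                      seed = derive_seed(seed, "library"))
write_plate_csv(registry, "results/compound_registry.csv")
cat("registry:", nrow(registry), "compounds,", sum(registry$active),
    "true actives,", sum(registry$toxic), "cytotoxic\n")

## one example field: a TGF-stimulated control well
field <- simulate_cell_field(80, frac_myo = differentiation_fraction(5),
                             dim = c(288, 288),
                             seed = derive_seed(seed, "A01", "field"),
                             well = "A01")
write_plate_csv(field$truth, "results/example_well_truth.csv")
write_field_tiff(field, "scratch/example_well_A01.tif")
cat("example well A01:", nrow(field$truth), "cells,",
    sum(field$truth$class == "myofibroblast"), "myofibroblasts",
    "(image in scratch/)\n")
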