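#!/usr/bin/env Rscript
# Builds the synthetic study fixtures -- the idealized biventricular mesh,
# the left/right Purkinje trees and the CV-calibration cable -- and writes
# them under results/fixtures/ in open formats (legacy VTK + CSV).
#
# Findings to expect: ~3000 lattice nodes split evenly across the three
# transmural layers, Purkinje terminals confined to the endocardium of
# their ventricle, and a His root at the basal septum.

suppressPackageStartupMessages(library(cardioem))
suppressPackageStartupMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "results/fixtures"))))

dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)

mesh <- make_biventricular_mesh(geometry_config(seed = opts$seed))
cat(sprintf("mesh: %d nodes, lattice spacing %.3f cm\n", mesh$n, mesh$h))
print(table(layer = mesh$cell_type))
print(table(region = mesh$region))
write_vtk_mesh(mesh, file.path(opts$outdir, "biventricular_mesh.vtk"))

tree <- make_purkinje_tree(mesh, purkinje_config(seed = opts$seed))
cat(sprintf("purkinje: %d nodes, %d terminals (%d left / %d right)\n",
            nrow(tree$nodes), nrow(tree$terminals),
            sum(tree$branch[tree$terminals$node] == "left"),
            sum(tree$branch[tree$terminals$node] == "right")))
write_purkinje_tables(tree, file.path(opts$outdir, "purkinje"))

cable <- make_cable(length = 2, n_nodes = 201)
cat(sprintf("cable: %d nodes, spacing %.4f cm\n", cable$n, cable$h))
write_vtk_mesh(cable, file.path(opts$outdir, "calibration_cable.vtk"))

ca <- make_ca_transient()
write.csv(ca, file.path(opts$outdir, "idealized_ca_transient.csv"),
          row.names = FALSE)
cat("fixtures written to ", opts$outdir, "\n")
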