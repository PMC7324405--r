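#!/usr/bin/env Rscript
## Stage 6: residues lining the high-flux entry pathway, with a
## conservation comparison between two cavity variants.
##
## The wall atoms are labelled as pseudo-residues; every residue with an
## atom within the Se:O-like contact distance (3.32 A) of a retained
## pathway segment is listed, and a toy correspondence table shows the
## conserved / non-conserved partition used when two homologous structures
## are compared.

library(ilsflux)

land <- read_volumetric("results/cavity_landscape.dx")
thermo <- thermo_params(300)
basins <- watershed(land, thermo)
saddles <- find_saddles(land, basins)
network <- build_network(land, basins, saddles)
model <- coarse_grain_solvent(
  build_markov_model(land, basins, saddles, 40, thermo),
  identify_solvent_basins(basins))
products <- intersect(as.character(
  select_product_basins(basins, data.frame(x = -1, y = 0, z = 0),
                        contact_distance = 2.5)),
  model$states)
pathways <- top_pathways(tpt_analysis(model, "solvent", products), 0.5)

traces <- pathway_traces_from(pathways, basins, network, land)
cat(sprintf("%d pathway trace(s), top flux %.3g\n", length(traces),
            pathways$pathways$flux[1]))

tpl <- cavity_template()
structure <- data.frame(chain = "A", resno = seq_len(nrow(tpl)),
                        resid = rep(c("GLY", "ALA", "VAL", "LEU", "SER",
                                      "THR"), length.out = nrow(tpl)),
                        element = "C", x = tpl$x, y = tpl$y, z = tpl$z)
lining <- lining_residues(traces, structure, contact_distance = 3.32,
                          flux_fraction = 0.5)
cat(sprintf("%d pseudo-residues line the entry pathway\n", nrow(lining)))
print(head(lining, 10), row.names = FALSE)
write.table(lining, "results/cavity_lining_residues.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## conservation demo: a variant with two substitutions near the channel
variant <- structure
variant$resid[c(25, 32)] <- "TRP"
mapping <- data.frame(resno_a = structure$resno, resno_b = variant$resno)
cons <- compare_residue_sets(structure[structure$resno %in% lining$resno, ],
                             variant, mapping)
cat(sprintf("conservation vs variant: %d conserved, %d substituted\n",
            nrow(cons$conserved), nrow(cons$non_conserved)))
write.table(rbind(cbind(cons$conserved, status = "conserved"),
                  cbind(cons$non_conserved, status = "non-conserved")),
            "results/cavity_residue_conservation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("-> results/cavity_lining_residues.tsv,",
    "results/cavity_residue_conservation.tsv\n")
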