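#!/usr/bin/env Rscript
# Stage 4: functional genomics of the epigenetically interacting drugs.
# Derives the three gene sets (all targets of interacting drugs, the
# epigenetic targets, and their set difference) against the background of
# all targets of the filtered drugs, runs the over/under-representation
# analysis over the synthetic ontology, assigns detail and headline roles
# and exports the colored DAGs.

suppressPackageStartupMessages(library(epidrugminer))
stopifnot(file.exists("results/inputs/synthetic_ontology.obo"))

registry <- load_packaged_registry()
sel <- select_drugs(parse_drug_database("results/inputs/synthetic_drugs.xml"))
map <- read.delim("results/inputs/synthetic_uniprot_map.tsv")
sets <- derive_ora_gene_sets(sel, registry, map)
cat(sprintf("gene sets: all %d, epigenetic %d, non-epigenetic %d, background %d\n",
            length(sets$all_targets), length(sets$epigenetic_targets),
            length(sets$non_epigenetic_targets), length(sets$background)))

dag <- parse_ontology("results/inputs/synthetic_ontology.obo")
ann <- read.delim("results/inputs/synthetic_annotations.tsv")
ann <- ann[ann$gene_id %in% sets$background, , drop = FALSE]
index <- propagate_annotations(dag, ann, sets$background)
cfg <- ora_config(p_threshold = 0.001, min_genes_per_term = 2)

for (nm in c("all_targets", "epigenetic_targets", "non_epigenetic_targets")) {
  gs <- sets[[nm]]
  if (length(gs) == 0) next
  res <- run_ora(gs, index, cfg, dag)
  roles <- annotate_dag_roles(res, dag, cfg,
                              universe_size = length(sets$background))
  rr <- roles$results
  n_sig <- sum(rr$direction != "none")
  cat(sprintf("%s: %d terms tested, %d significant (%d over / %d under), %d headlines\n",
              nm, nrow(rr), n_sig, sum(rr$direction == "over"),
              sum(rr$direction == "under"), sum(rr$is_headline)))
  write.table(rr, sprintf("results/ora_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(export_dag(roles$report), sprintf("results/dag_%s.dot", nm))
}
cat("wrote results/ora_*.tsv and results/dag_*.dot\n")
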