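#!/usr/bin/env Rscript
# Generates the full synthetic input set every downstream analysis script
# consumes: enzyme-registry XML, drug-database XML + UniProt map, ontology
# OBO + annotations, publication corpus, and country denominator tables.
# All generators are seeded, so re-running reproduces identical bytes.

suppressPackageStartupMessages(library(epidrugminer))

dir <- "results/inputs"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20210706

# the drug database is generated against the packaged registry of 68
# drug-interacting epigenetic enzymes, so targets carry real gene symbols
registry <- load_packaged_registry()
db <- generate_drug_database(n_drugs = 150, registry, seed = seed, dir = dir,
                             overlap_fraction = 0.4)

# ontology over the drug-target gene namespace (registry genes + decoys)
map <- read.delim(db$map_path)
ont <- generate_ontology_with_annotations(
  n_terms = 60, n_planted = 2, odds_ratio = 20, seed = seed, dir = dir,
  p_background = 0.10, universe = sort(map$gene_symbol),
  gene_set = registry$records$gene_symbol)

# corpus: planted epigenetics-and-drugs literature 1992-2020, saturating
# citation accrual with the biochemistry constant and Poisson noise
schedule <- stats::setNames(pmax(1, round(seq(1, 30, length.out = 29))),
                            1992:2020)
corpus <- generate_publication_corpus(
  schedule = schedule, n_background = 6, query_year = 2021,
  total_citations = 120, beta = 5.4, noise = "poisson", seed = seed,
  dir = dir)

country <- generate_country_tables(seed = seed, dir = dir)

truth <- list(drug_truth_total = db$truth$total,
              planted_terms = ont$truth$planted_terms,
              corpus_year_counts = as.list(corpus$truth$year_counts),
              beta = corpus$truth$beta)
jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                     pretty = TRUE)

cat("inputs written to", dir, "\n")
cat(sprintf("  planted interactions: %d; planted enriched term(s): %s\n",
            db$truth$total,
            paste(ont$truth$planted_terms, collapse = ", ")))
cat(sprintf("  corpus: %d planted matches over %d years\n",
            sum(corpus$truth$year_counts), length(schedule)))
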