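#' @name pipeline
#' @title End-to-end orchestration of the four analysis stages
#'
#' @description
#' Runs the four knowledge-discovery stages in their natural order —
#' enzyme registry, literature corpus and bibliometrics, drug-database
#' interactions, functional-genomics ORA — from one configuration, and
#' writes a report bundle of plain-text tables. The corpus and ontology
#' stages are optional: omitting their inputs skips them (and their
#' dependents) with a recorded notice.
NULL

#' Build a pipeline configuration
#'
#' @param registry_xml Path to a registry XML (alternatively pass
#'   `registry` as a ready `enzyme_registry`).
#' @param registry Optional `enzyme_registry` object (overrides
#'   `registry_xml`).
#' @param drugs_xml Path to the drug-database XML.
#' @param id_map Path to the UniProt-to-gene mapping TSV (optional).
#' @param corpus Path to the publication corpus TSV (optional stage).
#' @param population_table,output_table Paths to country denominator TSVs
#'   (optional).
#' @param obo,annotations Paths to the ontology and annotation TSV
#'   (optional stage).
#' @param query Query string (default [epigenetics_drug_query()]).
#' @param query_year Query year for \eqn{\Delta t}.
#' @param betas Discipline constants (default [beta_presets]).
#' @param allowed_groups Development groups kept by the drug filter.
#' @param ora ORA configuration ([ora_config()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(registry_xml = NULL, registry = NULL,
                            drugs_xml = NULL, id_map = NULL, corpus = NULL,
                            population_table = NULL, output_table = NULL,
                            obo = NULL, annotations = NULL,
                            query = epigenetics_drug_query(),
                            query_year = 2021, betas = beta_presets,
                            allowed_groups = c("approved", "investigational"),
                            ora = ora_config()) {
  cfg <- list(registry_xml = registry_xml, registry = registry,
              drugs_xml = drugs_xml, id_map = id_map, corpus = corpus,
              population_table = population_table,
              output_table = output_table, obo = obo,
              annotations = annotations, query = query,
              query_year = query_year, betas = betas,
              allowed_groups = allowed_groups, ora = ora)
  paths <- c(registry_xml, drugs_xml, id_map, corpus, population_table,
             output_table, obo, annotations)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort2(sprintf("configured input file(s) do not exist: %s",
                   paste(missing, collapse = ", ")), "config_error")
  if (is.null(registry) && is.null(registry_xml))
    abort2("a registry (object or XML path) is required", "config_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle`: list with `registry_summary`, `bibliometrics`
#'   (trend + country tables, when a corpus was supplied), `interactions`
#'   (matrix, histogram, coverage, group-association chi-square, when a
#'   drug database was supplied), `ora` (per gene-set results and DAG
#'   reports, when an ontology was supplied), `notices` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notices <- character()
  bundle <- list()

  # stage 1: enzyme registry
  registry <- config$registry %||% parse_enzyme_registry(config$registry_xml)
  bundle$registry_summary <- registry_summary(registry)

  # stage 2: corpus + bibliometrics (optional)
  if (!is.null(config$corpus)) {
    corpus <- read_corpus(config$corpus)
    flt <- filter_corpus(corpus, config$query)
    trend <- citation_trend(flt$matches, config$betas, config$query_year)
    country <- NULL
    if (nrow(flt$matches)) {
      hits <- table(flt$matches$country)
      hits <- stats::setNames(as.integer(hits), names(hits))
      if (!is.null(config$population_table))
        country <- normalize_country_counts(
          hits, read_tsv_file(config$population_table), "per_capita")
      else if (!is.null(config$output_table))
        country <- normalize_country_counts(
          hits, read_tsv_file(config$output_table), "per_output")
    }
    bundle$bibliometrics <- list(n_hits = nrow(flt$matches),
                                 year_counts = flt$year_counts,
                                 trend = trend, country = country)
  } else {
    notices <- c(notices, "no corpus supplied: bibliometric stage skipped")
  }

  # stage 3: drug interactions (optional)
  sel <- NULL
  if (!is.null(config$drugs_xml)) {
    drugs <- parse_drug_database(config$drugs_xml)
    sel <- select_drugs(drugs, allowed_groups = config$allowed_groups)
    id_map <- if (!is.null(config$id_map)) read_tsv_file(config$id_map)
    mat <- build_interaction_matrix(sel, registry, id_map)
    hist <- category_histogram(sel)
    cov <- coverage_statistics(sel, mat, registry,
                               n_all_drugs = length(drugs))
    chi <- group_interaction_chi_square(sel, mat)
    bundle$interactions <- list(matrix = mat, category_histogram = hist,
                                coverage = cov, chi_square = chi,
                                group_counts = attr(drugs, "group_counts"))
  } else {
    notices <- c(notices, "no drug database supplied: interaction stage skipped")
  }

  # stage 4: functional genomics ORA (optional; needs stage-3 gene sets)
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    if (is.null(sel)) {
      notices <- c(notices,
                   "ontology supplied without a drug database: ORA skipped")
    } else {
      dag <- parse_ontology(config$obo)
      ann <- read_tsv_file(config$annotations)
      sets <- derive_ora_gene_sets(sel, registry,
                                   if (!is.null(config$id_map))
                                     read_tsv_file(config$id_map))
      universe <- sets$background
      ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
      index <- propagate_annotations(dag, ann, universe,
                                     curated_only = config$ora$curated_only)
      bundle$ora <- lapply(sets[c("all_targets", "epigenetic_targets",
                                  "non_epigenetic_targets")], function(gs) {
        if (length(gs) == 0) return(NULL)
        res <- run_ora(gs, index, config$ora, dag)
        roles <- annotate_dag_roles(res, dag, config$ora,
                                    universe_size = length(universe))
        list(results = roles$results, report = roles$report)
      })
      bundle$ora_gene_sets <- sets
    }
  } else {
    notices <- c(notices, "no ontology supplied: ORA stage skipped")
  }

  bundle$notices <- notices
  cfg_prov <- config[c("registry_xml", "drugs_xml", "id_map", "corpus",
                       "population_table", "output_table", "obo",
                       "annotations", "query", "query_year",
                       "allowed_groups")]
  cfg_prov <- cfg_prov[!vapply(cfg_prov, is.null, logical(1))]
  cfg_prov$betas <- as.list(config$betas)
  cfg_prov$ora <- unclass(config$ora)
  bundle$provenance <- list(
    package_version = as.character(utils::packageVersion("epidrugminer")),
    config = cfg_prov,
    input_digests = input_digests(config))
  structure(bundle, class = "report_bundle")
}

input_digests <- function(config) {
  paths <- unlist(config[c("registry_xml", "drugs_xml", "id_map", "corpus",
                           "population_table", "output_table", "obo",
                           "annotations")])
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

#' Derive the three ORA gene sets from the interaction analysis
#'
#' Following the functional-genomics design: (i) all (mapped, human)
#' targets of drugs that interact with at least one registry enzyme,
#' (ii) the epigenetic targets among them (registry genes), and (iii) the
#' set difference (i) minus (ii); the background is the set of all mapped
#' human targets of every filtered drug.
#'
#' @param selected Filtered `drug_collection`.
#' @param registry An `enzyme_registry`.
#' @param id_map Optional UniProt-to-gene mapping data frame.
#' @return List with `all_targets`, `epigenetic_targets`,
#'   `non_epigenetic_targets`, `background` (sorted character vectors).
#' @export
derive_ora_gene_sets <- function(selected, registry, id_map = NULL) {
  map <- if (!is.null(id_map))
    stats::setNames(id_map$gene_symbol, id_map$uniprot_id) else character()
  gene_lists <- lapply(selected, function(d) {
    tg <- d$targets
    if (NROW(tg) == 0) return(character())
    genes <- unname(map[tg$uniprot_id])
    fallback <- is.na(genes)
    genes[fallback] <- tg$gene_symbol[fallback]
    genes[!is.na(genes) & nzchar(genes)]
  })
  enzymes <- registry$records$gene_symbol
  interacts <- vapply(gene_lists, function(g) any(g %in% enzymes), logical(1))
  all_targets <- sort(unique(unlist(gene_lists[interacts])))
  epigenetic <- intersect(all_targets, enzymes)
  list(all_targets = all_targets,
       epigenetic_targets = epigenetic,
       non_epigenetic_targets = setdiff(all_targets, epigenetic),
       background = sort(unique(unlist(gene_lists))))
}

#' Association between development group and epigenetic interaction
#'
#' The 2x2 table behind the bundled chi-square: drugs cross-classified by
#' development group (approved vs investigational-only) and by whether
#' they interact with a registry enzyme. `NULL` when a margin is zero.
#'
#' @param selected Filtered `drug_collection`.
#' @param matrix An `interaction_matrix` built from `selected`.
#' @return List with `table` and the [two_by_two_chi_square()] result, or
#'   `NULL` when the table is degenerate.
#' @export
group_interaction_chi_square <- function(selected, matrix) {
  if (length(selected) == 0) return(NULL)
  approved <- vapply(selected, function(d) "approved" %in% d$groups, logical(1))
  interacting <- vapply(selected, function(d) d$name, character(1)) %in%
    rownames(matrix$matrix)
  tab <- table(factor(approved, levels = c(TRUE, FALSE)),
               factor(interacting, levels = c(TRUE, FALSE)),
               dnn = c("approved", "interacting"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
  c(list(table = tab), two_by_two_chi_square(tab))
}

#' Write a report bundle to disk
#'
#' Emits the documented plain-text files (TSV/JSON/DOT) plus a
#' `manifest.json` listing what was written; sections absent from the
#' bundle are omitted. Overwrites idempotently; apart from the manifest's
#' timestamp, re-writing an identical bundle yields identical bytes.
#'
#' @param bundle A `report_bundle`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written file names, invisibly.
#' @export
write_reports <- function(bundle, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    abort2(sprintf("cannot create output directory '%s'", outdir), "io_error")
  written <- character()
  put_json <- function(x, name) {
    jsonlite::write_json(x, file.path(outdir, name), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    written <<- c(written, name)
  }
  put_tsv <- function(df, name) {
    write_tsv_file(df, file.path(outdir, name))
    written <<- c(written, name)
  }
  put_json(bundle$registry_summary, "registry_summary.json")
  if (!is.null(bundle$bibliometrics)) {
    b <- bundle$bibliometrics
    if (NROW(b$trend)) put_tsv(b$trend, "citation_trend.tsv")
    if (NROW(b$country)) put_tsv(b$country, "country_normalization.tsv")
    put_json(list(n_hits = b$n_hits, year_counts = as.list(b$year_counts)),
             "corpus_hits.json")
  }
  if (!is.null(bundle$interactions)) {
    it <- bundle$interactions
    m <- it$matrix$matrix
    if (length(m)) {
      mat_df <- data.frame(drug = rownames(m), as.data.frame(m),
                           check.names = FALSE)
      put_tsv(mat_df, "interaction_matrix.tsv")
      put_tsv(data.frame(drug = rownames(m),
                         n_interactions = unname(it$matrix$drug_marginals)),
              "drug_marginals.tsv")
      put_tsv(data.frame(enzyme = colnames(m),
                         n_interactions = unname(it$matrix$enzyme_marginals)),
              "enzyme_marginals.tsv")
    }
    if (NROW(it$category_histogram))
      put_tsv(it$category_histogram, "category_histogram.tsv")
    put_json(it$coverage, "coverage_statistics.json")
    if (!is.null(it$chi_square))
      put_json(it$chi_square[c("chi_square", "df", "p_value")],
               "chi_square.json")
  }
  if (!is.null(bundle$ora)) {
    for (nm in names(bundle$ora)) {
      sec <- bundle$ora[[nm]]
      if (is.null(sec)) next
      res <- sec$results
      # mirror the headline-table column layout
      out <- data.frame(`GO Term` = res$term_id,
                        `Molecular Function` = res$name %||% NA,
                        `Observed Annotations` = res$observed,
                        `Expected Annotations` = round(res$expected, 1),
                        `p-Value` = res$p_value,
                        `p-Adjusted` = res$p_adjusted,
                        Direction = res$direction,
                        Remarkableness = res$remarkableness,
                        Detail = res$is_detail, Headline = res$is_headline,
                        check.names = FALSE)
      put_tsv(out, sprintf("ora_%s.tsv", nm))
      writeLines(export_dag(sec$report),
                 file.path(outdir, sprintf("dag_%s.dot", nm)))
      written <- c(written, sprintf("dag_%s.dot", nm))
    }
  }
  put_json(bundle$provenance, "provenance.json")
  manifest <- list(written = sort(written),
                   notices = bundle$notices,
                   timestamp = format(Sys.time(), tz = "UTC"))
  put_json(manifest, "manifest.json")
  invisible(written)
}
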