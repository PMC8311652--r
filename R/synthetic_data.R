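#' @name synthetic_data
#' @title Seeded generators for every pipeline input
#'
#' @description
#' Generators emulating the five input kinds the pipeline consumes:
#' an enzyme-registry XML, a drug-database XML with a UniProt-to-gene
#' mapping table, an ontology (OBO) with a gene-annotation table, a
#' publication corpus, and country denominator tables. Every generator is
#' a pure function of its arguments and seed (byte-identical re-runs) and
#' returns a truth record that downstream tests use as ground truth:
#' planted interaction matrices, per-year match schedules, planted
#' enriched terms, and planted accrual parameters.
NULL

# Evaluate `code` under a private RNG stream; the caller's RNG state is
# untouched (test isolation).
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic enzyme-registry XML
#'
#' Synthetic gene symbols (`SYNG...`) receive actions allocated
#' deterministically from `action_mix` by largest remainder, so the
#' default mix at `n = 68` reproduces the packaged registry's composition
#' (8 DNA-substrate, 60 histone-substrate enzymes).
#'
#' @param n Number of enzymes.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param action_mix Named numeric vector of action proportions (default:
#'   the packaged registry's composition).
#' @return List with `path` (registry XML) and `truth` (data frame
#'   `gene_symbol`, `enzyme_action`, `uniprot_id`, `ncbi_gene_id`).
#' @export
generate_enzyme_registry <- function(n = 68, seed = 1, dir = tempdir(),
                                     action_mix = NULL) {
  if (is.null(action_mix)) {
    s <- registry_summary(load_packaged_registry())
    action_mix <- s$action_counts / sum(s$action_counts)
  }
  action_mix <- action_mix / sum(action_mix)
  counts <- floor(action_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- action_mix * n - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  actions <- rep(names(counts), counts)
  truth <- data.frame(
    gene_symbol = sprintf("SYNG%03d", seq_len(n)),
    gene_name = sprintf("synthetic enzyme %d", seq_len(n)),
    ncbi_gene_id = 900000L + seq_len(n),
    uniprot_id = sprintf("SYNP%05d", seq_len(n)),
    enzyme_action = actions[seq_len(n)] %||% character(),
    stringsAsFactors = FALSE)
  reg <- new_enzyme_registry(truth, source_label = sprintf("synthetic-seed-%d", seed))
  path <- file.path(dir, "synthetic_registry.xml")
  write_enzyme_registry_xml(reg, path)
  list(path = path, truth = truth)
}

#' Generate a synthetic drug-database XML with planted interactions
#'
#' Each drug receives development groups from `group_probs`
#' (multi-membership allowed), categories from a small pool, and a target
#' list mixing registry genes (each drug interacts with registry enzymes
#' with probability `overlap_fraction`) and decoy genes from a disjoint
#' `DECOY...` namespace; a fraction of targets is assigned a non-human
#' organism. The truth record stores the exact interaction matrix expected
#' after filtering to `allowed_groups` and human targets.
#'
#' @param n_drugs Number of drugs.
#' @param registry An `enzyme_registry` (e.g. a generated one).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param overlap_fraction Probability that a drug is an epigenetic
#'   interactor (then it targets 1..5 registry enzymes).
#' @param group_probs Named inclusion probabilities per development group;
#'   drugs drawing no group get "experimental".
#' @param nonhuman_fraction Fraction of targets assigned organism "Mouse".
#' @param allowed_groups Groups used for the truth-matrix bookkeeping.
#' @return List with `path` (drug XML), `map_path` (UniProt-to-gene TSV
#'   covering registry and decoy targets) and `truth` (list: `matrix`
#'   expected after filtering, `n_interacting_drugs`, `n_interacting_enzymes`,
#'   `total`).
#' @export
generate_drug_database <- function(n_drugs = 40, registry, seed = 1,
                                   dir = tempdir(), overlap_fraction = 0.5,
                                   group_probs = c(approved = 0.35,
                                     investigational = 0.35,
                                     experimental = 0.45, nutraceutical = 0.02,
                                     vet_approved = 0.03, withdrawn = 0.02),
                                   nonhuman_fraction = 0.15,
                                   allowed_groups = c("approved",
                                                      "investigational")) {
  genes <- registry$records$gene_symbol
  decoys <- sprintf("DECOY%03d", 1:60)
  all_genes <- c(genes, decoys)
  uniprot <- stats::setNames(sprintf("SYNU%05d", seq_along(all_genes)), all_genes)
  cat_pool <- c("antineoplastic agents", "enzyme inhibitors",
                "cytochrome P-450 substrates", "immunosuppressive agents",
                "benzene and substituted derivatives", "kinase inhibitors",
                "myelosuppressive agents")
  with_local_seed(seed, {
    drugs <- vector("list", n_drugs)
    pairs <- list()
    for (i in seq_len(n_drugs)) {
      gr <- names(group_probs)[stats::runif(length(group_probs)) < group_probs]
      if (length(gr) == 0) gr <- "experimental"
      is_interactor <- stats::runif(1) < overlap_fraction && length(genes) > 0
      epi <- if (is_interactor)
        sample(genes, min(length(genes), sample(1:5, 1))) else character()
      dec <- sample(decoys, sample(0:6, 1))
      tg_genes <- c(epi, dec)
      organism <- rep("Humans", length(tg_genes))
      if (length(tg_genes))
        organism[stats::runif(length(tg_genes)) < nonhuman_fraction] <- "Mouse"
      drugs[[i]] <- list(
        drug_id = sprintf("SYNDB%05d", i),
        name = sprintf("syndrug-%03d", i),
        groups = gr,
        categories = sort(sample(cat_pool, sample(1:3, 1))),
        targets = data.frame(uniprot_id = unname(uniprot[tg_genes]),
                             organism = organism,
                             gene_symbol = rep(NA_character_,
                                               length(tg_genes)),
                             stringsAsFactors = FALSE))
      # truth bookkeeping: interactions surviving the group + human filter
      if (any(gr %in% allowed_groups)) {
        kept <- intersect(epi, tg_genes[organism == "Humans"])
        if (length(kept))
          pairs[[length(pairs) + 1L]] <-
            data.frame(drug = drugs[[i]]$name, enzyme = kept,
                       stringsAsFactors = FALSE)
      }
    }
    truth_matrix <- if (length(pairs)) {
      inc <- unique(do.call(rbind, pairs))
      dn <- sort(unique(inc$drug)); en <- sort(unique(inc$enzyme))
      mm <- matrix(0L, length(dn), length(en), dimnames = list(dn, en))
      mm[cbind(match(inc$drug, dn), match(inc$enzyme, en))] <- 1L
      mm
    } else matrix(0L, 0, 0)
    path <- file.path(dir, "synthetic_drugs.xml")
    write_drug_database_xml(structure(drugs, class = "drug_collection"), path)
    map <- data.frame(uniprot_id = unname(uniprot),
                      gene_symbol = all_genes,
                      ncbi_gene_id = 800000L + seq_along(all_genes),
                      stringsAsFactors = FALSE)
    map_path <- file.path(dir, "synthetic_uniprot_map.tsv")
    write_tsv_file(map, map_path)
    list(path = path, map_path = map_path,
         truth = list(matrix = truth_matrix,
                      n_interacting_drugs = nrow(truth_matrix),
                      n_interacting_enzymes = ncol(truth_matrix),
                      total = sum(truth_matrix)))
  })
}

#' Generate a synthetic ontology with annotations and planted enrichment
#'
#' Builds a random rooted DAG (each non-root term attaches to 1-2 existing
#' terms), a gene universe, background annotations at rate `p_background`,
#' and plants enrichment of a designated study set at `odds_ratio` on
#' `n_planted` leaf-ish terms: study genes are annotated to a planted term
#' with the probability whose odds are `odds_ratio` times the background
#' odds.
#'
#' @param n_terms Number of terms (besides the root).
#' @param n_genes Universe size (ignored when `universe` is given).
#' @param set_size Size of the designated study set, taken as the first
#'   `set_size` universe genes (ignored when `gene_set` is given).
#' @param n_planted Number of planted enriched terms.
#' @param odds_ratio Planted enrichment odds ratio.
#' @param p_background Background annotation probability per (gene, term).
#' @param max_parents Maximal parents per term (1-2 typical).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param universe Optional externally supplied gene universe (e.g. the
#'   drug-target background), replacing the synthetic `G...` ids.
#' @param gene_set Optional externally supplied study set (subset of
#'   `universe`).
#' @return List with `obo_path`, `annotation_path`, and `truth` (list:
#'   `planted_terms`, `gene_set`, `universe`, `edges` data frame).
#' @export
generate_ontology_with_annotations <- function(n_terms = 60, n_genes = 1000,
                                               set_size = 50, n_planted = 1,
                                               odds_ratio = 8,
                                               p_background = 0.08,
                                               max_parents = 2, seed = 1,
                                               dir = tempdir(),
                                               universe = NULL,
                                               gene_set = NULL) {
  ids <- c("SYN:0000000", sprintf("SYN:%07d", seq_len(n_terms)))
  universe <- universe %||% sprintf("G%05d", seq_len(n_genes))
  gene_set <- gene_set %||% universe[seq_len(min(set_size, length(universe)))]
  stopifnot(all(gene_set %in% universe), n_planted <= n_terms)
  set_size <- length(gene_set)
  with_local_seed(seed, {
    edges <- list()
    for (i in seq_len(n_terms) + 1L) {
      np <- sample(seq_len(min(max_parents, i - 1L)), 1)
      parents <- sample(ids[seq_len(i - 1L)], np)
      rel <- sample(c("is_a", "part_of"), np, replace = TRUE, prob = c(0.8, 0.2))
      edges[[length(edges) + 1L]] <- data.frame(child = ids[i],
                                                parent = parents,
                                                relation = rel,
                                                stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    # planted terms: prefer leaves (no children) so the signal is local
    leaves <- setdiff(ids[-1], unique(edges$parent))
    planted <- if (n_planted > 0)
      sample(if (length(leaves) >= n_planted) leaves else ids[-1], n_planted)
      else character()
    odds_bg <- p_background / (1 - p_background)
    p_planted <- odds_ratio * odds_bg / (1 + odds_ratio * odds_bg)
    ann <- list()
    for (t in ids[-1]) {
      p_set <- if (t %in% planted) p_planted else p_background
      in_set <- gene_set[stats::runif(set_size) < p_set]
      rest <- setdiff(universe, gene_set)
      in_rest <- rest[stats::runif(length(rest)) < p_background]
      g <- c(in_set, in_rest)
      if (length(g))
        ann[[length(ann) + 1L]] <- data.frame(gene_id = g, term_id = t,
                                              evidence = "IDA",
                                              stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann) %||%
      data.frame(gene_id = character(), term_id = character(),
                 evidence = character())
    obo_path <- file.path(dir, "synthetic_ontology.obo")
    obo <- c("format-version: 1.2", "")
    for (i in seq_along(ids)) {
      obo <- c(obo, "[Term]", paste0("id: ", ids[i]),
               paste0("name: synthetic term ", i - 1L),
               "namespace: molecular_function")
      ed <- edges[edges$child == ids[i], , drop = FALSE]
      for (j in seq_len(nrow(ed))) {
        obo <- c(obo, if (ed$relation[j] == "is_a")
          paste0("is_a: ", ed$parent[j], " ! parent")
          else paste0("relationship: ", ed$relation[j], " ", ed$parent[j],
                      " ! parent"))
      }
      obo <- c(obo, "")
    }
    writeLines(obo, obo_path)
    annotation_path <- file.path(dir, "synthetic_annotations.tsv")
    write_tsv_file(annotations, annotation_path)
    list(obo_path = obo_path, annotation_path = annotation_path,
         truth = list(planted_terms = planted, gene_set = gene_set,
                      universe = universe, edges = edges))
  })
}

#' Generate a synthetic publication corpus
#'
#' Plants `schedule[y]` records per year whose text satisfies the default
#' epigenetics-and-drugs search string, plus `n_background` records per
#' scheduled year that do not (either by lacking the query tokens or by
#' being reviews at `review_fraction`). Cumulative citations follow the
#' saturating accrual curve \eqn{C = N(1 - e^{-\Delta t/\beta})}
#' (rounded), optionally with Poisson noise around the curve.
#'
#' @param schedule Named integer vector: planted matching records per year
#'   (names are years).
#' @param n_background Non-matching records added per scheduled year.
#' @param query_year Year of the simulated query (sets \eqn{\Delta t}).
#' @param total_citations Planted eventual total \eqn{N} per paper; a
#'   scalar, or a vector recycled over matching records.
#' @param beta Planted discipline constant.
#' @param noise `"none"` (deterministic rounding of the curve) or
#'   `"poisson"` (Poisson counts with the curve as mean).
#' @param review_fraction Fraction of background records typed "Review".
#' @param countries Character vector of country names sampled for records.
#' @param country_weights Sampling weights for `countries`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with `path` (corpus TSV) and `truth` (list:
#'   `year_counts` planted per-year match schedule, `N`, `beta`,
#'   `country_hits` per-country planted match counts).
#' @export
generate_publication_corpus <- function(schedule = c("1999" = 2),
                                        n_background = 3, query_year = 2021,
                                        total_citations = 100, beta = 5.4,
                                        noise = c("none", "poisson"),
                                        review_fraction = 0.2,
                                        countries = c("United States",
                                          "United Kingdom", "Netherlands",
                                          "Germany", "Greece"),
                                        country_weights = c(5, 3, 1, 1, 1),
                                        seed = 1, dir = tempdir()) {
  noise <- match.arg(noise)
  years <- as.integer(names(schedule))
  stopifnot(all(years < query_year))
  match_text <- paste("epigenetic histone modification by a methylase",
                      "drug in tumor cells")
  bg_texts <- c("transcription factor binding in yeast growth assays",
                "clinical outcomes of surgical intervention cohorts")
  with_local_seed(seed, {
    rows <- list()
    n_match_total <- sum(schedule)
    Ns <- rep_len(total_citations, n_match_total)
    k <- 0L
    for (yi in seq_along(years)) {
      y <- years[yi]; dt <- query_year - y
      for (j in seq_len(schedule[yi])) {
        k <- k + 1L
        mu <- Ns[k] * (1 - exp(-dt / beta))
        cit <- if (noise == "poisson") stats::rpois(1, mu) else round(mu)
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = sprintf("PMID%06d", length(rows) + 1L),
          year = y,
          country = sample(countries, 1, prob = country_weights),
          publication_types = "Journal Article",
          text = match_text,
          cumulative_citations = cit,
          included = TRUE, planted_match = TRUE,
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(n_background)) {
        is_review <- stats::runif(1) < review_fraction
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = sprintf("PMID%06d", length(rows) + 1L),
          year = y,
          country = sample(countries, 1, prob = country_weights),
          publication_types = if (is_review) "Journal Article;Review"
                              else "Journal Article",
          # reviews carry matching text but are excluded by the [PT] clause
          text = if (is_review) match_text else sample(bg_texts, 1),
          cumulative_citations = stats::rpois(1, 10),
          included = TRUE, planted_match = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    corpus <- do.call(rbind, rows)
    path <- file.path(dir, "synthetic_corpus.tsv")
    write_tsv_file(corpus, path)
    planted <- corpus[corpus$planted_match, , drop = FALSE]
    tab <- table(planted$year)
    chits <- table(planted$country)
    list(path = path,
         truth = list(
           year_counts = stats::setNames(as.integer(tab), names(tab)),
           N = Ns, beta = beta, query_year = query_year,
           country_hits = stats::setNames(as.integer(chits), names(chits))))
  })
}

#' Generate country population and national-output tables
#'
#' @param countries Country names.
#' @param years Years covered by the population table.
#' @param base_population Approximate population scale per country
#'   (recycled).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with `population_path` (TSV `country`, `year`,
#'   `population`) and `output_path` (TSV `country`, `n_publications`).
#' @export
generate_country_tables <- function(countries = c("United States",
                                      "United Kingdom", "Netherlands",
                                      "Germany", "Greece"),
                                    years = 1992:2020,
                                    base_population = c(300e6, 65e6, 17e6,
                                                        82e6, 11e6),
                                    seed = 1, dir = tempdir()) {
  base <- rep_len(base_population, length(countries))
  with_local_seed(seed, {
    pop <- do.call(rbind, lapply(seq_along(countries), function(i) {
      data.frame(country = countries[i], year = years,
                 population = round(base[i] * (1 + 0.002 * (years - years[1]))),
                 stringsAsFactors = FALSE)
    }))
    out <- data.frame(country = countries,
                      n_publications = stats::rpois(length(countries),
                                                    lambda = 5000),
                      stringsAsFactors = FALSE)
    population_path <- file.path(dir, "synthetic_population.tsv")
    output_path <- file.path(dir, "synthetic_output.tsv")
    write_tsv_file(pop, population_path)
    write_tsv_file(out, output_path)
    list(population_path = population_path, output_path = output_path)
  })
}

#' Read a publication corpus TSV
#'
#' @param path Corpus TSV as written by [generate_publication_corpus()]
#'   (columns `record_id`, `year`, `country`, `publication_types`, `text`,
#'   `cumulative_citations`, optional `included`).
#' @return Data frame.
#' @export
read_corpus <- function(path) read_tsv_file(path)
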