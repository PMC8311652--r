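#' @name ora
#' @title Over/under-representation analysis with headline selection
#'
#' @description
#' For each ontology term the number of genes of a study set annotated to
#' it (after true-path propagation) is compared with the expectation for a
#' random set of the same size drawn from the background universe, via a
#' two-sided Fisher exact test on the 2x2 table (in set x annotated).
#' P-values are Bonferroni-corrected over the terms actually tested.
#' Significant terms are classified as over- or underrepresented by the
#' sign of observed minus expected. Significant terms with no significant
#' descendant are "details" (the ends of significant branches); on every
#' path from a detail up to the root, the significant term with the highest
#' remarkableness is the branch's "headline".
NULL

#' ORA configuration
#'
#' @param p_threshold Significance level applied to the corrected p-value
#'   (default 0.001).
#' @param min_genes_per_term Minimum propagated universe genes a term needs
#'   to be tested (default 2).
#' @param namespace Optional namespace filter (e.g. `"molecular_function"`).
#' @param curated_only Restrict annotations to curated evidence labels.
#' @return List of class `ora_config`.
#' @export
ora_config <- function(p_threshold = 0.001, min_genes_per_term = 2,
                       namespace = NULL, curated_only = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1, min_genes_per_term >= 1)
  structure(list(p_threshold = p_threshold,
                 min_genes_per_term = min_genes_per_term,
                 namespace = namespace, curated_only = curated_only),
            class = "ora_config")
}

#' Run the over/under-representation analysis
#'
#' @param gene_set Character vector of study genes; must be a subset of the
#'   index's universe.
#' @param index An `annotation_index` from [propagate_annotations()].
#' @param config An [ora_config()].
#' @param dag Optional `ontology_dag` supplying term names/namespaces (and
#'   required when `config$namespace` is set).
#' @return Data frame with one row per tested term: `term_id`, `name`,
#'   `namespace`, `n_annotated` (propagated universe genes at the term),
#'   `observed`, `expected`, `p_value`, `p_adjusted`, `direction`
#'   (`over`/`under`/`none`), plus attribute `m_tested`.
#' @export
run_ora <- function(gene_set, index, config = ora_config(), dag = NULL) {
  universe <- index$universe
  N <- length(universe)
  if (N < 2) abort2("universe must contain at least 2 genes", "domain_error")
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    abort2(sprintf("gene(s) outside the universe: %s",
                   paste(utils::head(outside, 5), collapse = ", ")),
           "gene_outside_universe")
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  terms <- names(index$propagated)
  info <- NULL
  if (!is.null(dag)) {
    info <- dag$terms[match(terms, dag$terms$term_id), , drop = FALSE]
    if (!is.null(config$namespace)) {
      keep <- !is.na(info$namespace) & info$namespace == config$namespace
      terms <- terms[keep]; info <- info[keep, , drop = FALSE]
    }
  } else if (!is.null(config$namespace)) {
    abort2("namespace filter requires the ontology DAG", "domain_error")
  }
  K <- vapply(index$propagated[terms],
              function(g) length(intersect(g, universe)), integer(1))
  tested <- K >= config$min_genes_per_term
  terms <- terms[tested]; K <- K[tested]
  if (!is.null(info)) info <- info[tested, , drop = FALSE]
  m <- length(terms)
  res <- lapply(seq_len(m), function(i) {
    ann <- intersect(index$propagated[[terms[i]]], universe)
    a <- length(intersect(gene_set, ann))        # in set, annotated
    tab <- matrix(c(a, n - a, K[i] - a, N - n - (K[i] - a)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(term_id = terms[i], n_annotated = K[i], observed = a,
               expected = n * K[i] / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res) %||%
    data.frame(term_id = character(), n_annotated = integer(),
               observed = integer(), expected = numeric(),
               p_value = numeric())
  res$p_adjusted <- pmin(1, res$p_value * m)
  significant <- res$p_adjusted < config$p_threshold
  res$direction <- ifelse(!significant, "none",
                          ifelse(res$observed > res$expected, "over",
                                 ifelse(res$observed < res$expected, "under",
                                        "none")))
  if (!is.null(info)) {
    res$name <- info$name
    res$namespace <- info$namespace
    res <- res[, c("term_id", "name", "namespace", "n_annotated", "observed",
                   "expected", "p_value", "p_adjusted", "direction")]
  }
  attr(res, "m_tested") <- m
  attr(res, "config") <- config
  rownames(res) <- NULL
  res
}

#' Default remarkableness score
#'
#' Combines statistical certainty with the information value of a term:
#' \eqn{R = (1 - p_{adj}) \times IC} with
#' \eqn{IC = -\log_2(K_{term}/N)}, so general terms annotating most of the
#' universe score low however significant they are. Supplied as the default
#' of a pluggable scoring interface.
#'
#' @param p_adjusted Corrected p-values.
#' @param n_annotated Universe genes annotated at the term (propagated).
#' @param universe_size Size of the background universe.
#' @return Numeric scores.
#' @export
remarkableness_score <- function(p_adjusted, n_annotated, universe_size) {
  (1 - p_adjusted) * (-log2(n_annotated / universe_size))
}

#' Assign detail and headline roles over the DAG
#'
#' Details are significant terms with no significant descendant.
#' For every path from a detail up to a root, the significant node with the
#' highest remarkableness on that path becomes a headline (ties broken by
#' smaller corrected p, then by greater depth, i.e. distance from the root
#' along the path).
#'
#' @param results Data frame from [run_ora()].
#' @param dag The `ontology_dag` the results were computed over.
#' @param config The [ora_config()] used (for the significance threshold).
#' @param score_fn Remarkableness scoring function taking
#'   `(p_adjusted, n_annotated, universe_size)`; default
#'   [remarkableness_score()].
#' @param universe_size Size of the gene universe (needed by the default
#'   score); inferred from `results` attribute when available.
#' @return List with `results` (input plus `remarkableness`, `is_detail`,
#'   `is_headline`) and `report` (a `dag_report`: per-node class table for
#'   export).
#' @export
annotate_dag_roles <- function(results, dag, config = ora_config(),
                               score_fn = remarkableness_score,
                               universe_size = NULL) {
  unknown <- setdiff(results$term_id, dag$terms$term_id)
  if (length(unknown))
    abort2(sprintf("results reference term(s) not in the DAG: %s",
                   paste(unknown, collapse = ", ")), "unknown_term")
  if (is.null(universe_size)) {
    # largest propagated count is a lower bound; require explicit size if
    # the root was filtered out of the results
    universe_size <- max(results$n_annotated, 1L)
  }
  sig <- results$term_id[results$direction %in% c("over", "under")]
  res <- results
  res$remarkableness <- rep(NA_real_, nrow(res))
  idx_sig <- res$term_id %in% sig
  res$remarkableness[idx_sig] <- score_fn(res$p_adjusted[idx_sig],
                                          res$n_annotated[idx_sig],
                                          universe_size)
  g <- dag_graph(dag)
  # descendants: vertices that reach the term over child->parent edges
  has_sig_descendant <- vapply(sig, function(t) {
    desc <- names(igraph::subcomponent(g, t, mode = "in"))
    any(setdiff(desc, t) %in% sig)
  }, logical(1))
  details <- sig[!has_sig_descendant]
  roots <- dag_roots(dag)
  headlines <- character()
  padj <- stats::setNames(res$p_adjusted, res$term_id)
  rmk <- stats::setNames(res$remarkableness, res$term_id)
  for (d in details) {
    reachable_roots <- intersect(
      names(igraph::subcomponent(g, d, mode = "out")), roots)
    for (r in reachable_roots) {
      paths <- igraph::all_simple_paths(g, from = d, to = r, mode = "out")
      for (p in paths) {
        nodes <- names(p)                       # detail first, root last
        cand <- nodes[nodes %in% sig]
        if (length(cand) == 0) next
        depth <- length(nodes) - match(cand, nodes)   # root depth 0
        ord <- order(-rmk[cand], padj[cand], -depth)
        headlines <- c(headlines, cand[ord[1]])
      }
    }
  }
  headlines <- unique(headlines)
  res$is_detail <- res$term_id %in% details
  res$is_headline <- res$term_id %in% headlines
  report <- data.frame(
    term_id = sort(dag$terms$term_id),
    stringsAsFactors = FALSE)
  ridx <- match(report$term_id, res$term_id)
  report$direction <- ifelse(is.na(ridx), "none", res$direction[ridx])
  report$is_detail <- !is.na(ridx) & res$is_detail[ridx]
  report$is_headline <- !is.na(ridx) & res$is_headline[ridx]
  report$class <- ifelse(report$is_headline, "headline",
                   ifelse(report$is_detail, "detail",
                    ifelse(report$direction == "over", "overrepresented",
                     ifelse(report$direction == "under", "underrepresented",
                            "structural"))))
  report <- structure(list(nodes = report,
                           edges = dag$edges[
                             dag$edges$relation %in% propagation_relations, ,
                             drop = FALSE]),
                      class = "dag_report")
  list(results = res, report = report)
}

#' Export a colored DAG report as a DOT document
#'
#' One node per term with class-coded fill colors (headline yellow, detail
#' blue, overrepresented red, underrepresented green, structural white; the
#' border repeats the direction color), one edge per `is_a`/`part_of` edge,
#' nodes and edges in deterministic (sorted) order.
#'
#' @param report A `dag_report` from [annotate_dag_roles()].
#' @return Character vector of DOT lines (also suitable for
#'   [writeLines()]).
#' @export
export_dag <- function(report) {
  fills <- c(structural = "white", overrepresented = "red",
             underrepresented = "green", detail = "lightblue",
             headline = "yellow")
  nd <- report$nodes[order(report$nodes$term_id), , drop = FALSE]
  border <- ifelse(nd$direction == "over", "red",
                   ifelse(nd$direction == "under", "green", "black"))
  node_lines <- sprintf(
    '  "%s" [style=filled, fillcolor=%s, color=%s, shape=ellipse];',
    nd$term_id, fills[nd$class], border)
  ed <- report$edges[order(report$edges$child, report$edges$parent), ,
                     drop = FALSE]
  edge_lines <- sprintf('  "%s" -> "%s";', ed$child, ed$parent)
  c("digraph ontology {", "  rankdir=BT;", node_lines, edge_lines, "}")
}
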