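#' @name ontology
#' @title Ontology DAG parsing and true-path annotation propagation
#'
#' @description
#' Terms of a gene ontology form a polyhierarchy: a rooted directed acyclic
#' graph whose edges are `is_a`, `part_of` and `regulates` relations.
#' Under the true-path rule a gene annotated to a term is implicitly
#' annotated to every ancestor reached over `is_a`/`part_of` edges;
#' `regulates` edges are parsed but excluded from propagation, the standard
#' practice.
NULL

propagation_relations <- c("is_a", "part_of")

#' Parse an OBO-format ontology
#'
#' Supports the OBO 1.2 tags `id`, `name`, `namespace`, `is_a`,
#' `relationship` (`part_of`, `regulates`) and `is_obsolete` inside
#' `[Term]` stanzas. Obsolete terms are dropped; stanzas without an id are
#' skipped with a warning; a cycle over `is_a`/`part_of` edges is a
#' structural error naming the terms involved.
#'
#' @param path Path to an OBO file.
#' @return An `ontology_dag`: list with `terms` (data frame `term_id`,
#'   `name`, `namespace`) and `edges` (data frame `child`, `parent`,
#'   `relation`).
#' @export
parse_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  n_skipped <- 0L
  terms <- list(); edges <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    tagval <- function(tag) {
      hit <- chunk[startsWith(chunk, paste0(tag, ": "))]
      sub(paste0("^", tag, ": "), "", hit)
    }
    id <- tagval("id")
    if (length(id) == 0 || !nzchar(id[1])) { n_skipped <- n_skipped + 1L; next }
    id <- id[1]
    if (any(tolower(tagval("is_obsolete")) == "true")) next
    # strip trailing "! name" comments from edge targets
    clean <- function(x) trimws(sub("!.*$", "", x))
    isa <- clean(tagval("is_a"))
    rel <- tagval("relationship")
    relmat <- if (length(rel)) {
      parts <- strsplit(clean(rel), "\\s+")
      data.frame(relation = vapply(parts, `[`, "", 1),
                 parent = vapply(parts, `[`, "", 2),
                 stringsAsFactors = FALSE)
    } else data.frame(relation = character(), parent = character())
    ed <- rbind(
      if (length(isa)) data.frame(relation = "is_a", parent = isa,
                                  stringsAsFactors = FALSE),
      relmat)
    if (NROW(ed)) {
      ed$child <- id
      edges[[length(edges) + 1L]] <- ed[, c("child", "parent", "relation")]
    }
    terms[[length(terms) + 1L]] <- data.frame(
      term_id = id,
      name = if (length(tagval("name"))) tagval("name")[1] else NA_character_,
      namespace = if (length(tagval("namespace"))) tagval("namespace")[1]
                  else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0)
    warn2(sprintf("skipped %d [Term] stanza(s) without an id", n_skipped),
          "obo_stanza_skipped")
  terms <- do.call(rbind, terms) %||%
    data.frame(term_id = character(), name = character(),
               namespace = character())
  edges <- do.call(rbind, edges) %||%
    data.frame(child = character(), parent = character(),
               relation = character())
  # drop edges into obsolete/unknown terms
  edges <- edges[edges$parent %in% terms$term_id &
                   edges$child %in% terms$term_id, , drop = FALSE]
  rownames(terms) <- rownames(edges) <- NULL
  dag <- structure(list(terms = terms, edges = edges), class = "ontology_dag")
  check_acyclic(dag)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

dag_graph <- function(dag, relations = propagation_relations) {
  ed <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(ed[, c("child", "parent")], directed = TRUE,
                                vertices = dag$terms$term_id)
}

check_acyclic <- function(dag) {
  g <- dag_graph(dag)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc)
    abort2(sprintf("ontology contains a cycle over is_a/part_of involving: %s",
                   paste(unique(as.vector(ends)), collapse = ", ")),
           "ontology_cycle")
  }
  invisible(TRUE)
}

#' Root terms of an ontology DAG
#'
#' @param dag An `ontology_dag`.
#' @return Character vector of terms without parents (over propagation
#'   relations).
#' @export
dag_roots <- function(dag) {
  ed <- dag$edges[dag$edges$relation %in% propagation_relations, , drop = FALSE]
  setdiff(dag$terms$term_id, unique(ed$child))
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' Each term's propagated gene set is its directly annotated genes joined
#' with the propagated sets of all its children over `is_a`/`part_of`
#' edges.
#'
#' @param dag An `ontology_dag`.
#' @param annotations Data frame with columns `gene_id`, `term_id` and
#'   optionally `evidence`.
#' @param universe Character vector: the background gene universe. Every
#'   directly annotated gene must be in it.
#' @param curated_only Keep only annotations whose evidence label is in
#'   `curated_evidence` (electronic annotations excluded).
#' @param curated_evidence Evidence labels counted as manually curated.
#' @return An `annotation_index`: list with `direct` and `propagated`
#'   (named lists of gene vectors per term) and `universe`.
#' @export
propagate_annotations <- function(dag, annotations, universe,
                                  curated_only = FALSE,
                                  curated_evidence = c("EXP", "IDA", "IPI",
                                    "IMP", "IGI", "IEP", "TAS", "IC")) {
  bad_gene <- setdiff(unique(annotations$gene_id), universe)
  if (length(bad_gene))
    abort2(sprintf("annotated gene(s) outside the universe: %s",
                   paste(utils::head(bad_gene, 5), collapse = ", ")),
           "gene_outside_universe")
  if (curated_only && "evidence" %in% names(annotations))
    annotations <- annotations[annotations$evidence %in% curated_evidence, ,
                               drop = FALSE]
  unknown <- !annotations$term_id %in% dag$terms$term_id
  if (any(unknown)) {
    warn2(sprintf("dropped %d annotation(s) to unknown term(s): %s",
                  sum(unknown),
                  paste(unique(annotations$term_id[unknown]), collapse = ", ")),
          "unknown_term_annotation")
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  direct <- lapply(split(annotations$gene_id, annotations$term_id), unique)
  g <- dag_graph(dag)
  order_ids <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]
  prop <- stats::setNames(vector("list", nrow(dag$terms)), dag$terms$term_id)
  ed <- dag$edges[dag$edges$relation %in% propagation_relations, , drop = FALSE]
  children_of <- split(ed$child, ed$parent)
  for (t in order_ids) {   # children precede parents in this order
    s <- direct[[t]]
    for (ch in children_of[[t]]) s <- c(s, prop[[ch]])
    prop[[t]] <- unique(s) %||% character()
  }
  structure(list(direct = direct, propagated = prop, universe = universe),
            class = "annotation_index")
}
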