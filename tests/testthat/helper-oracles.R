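# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the query oracle works on materialized match
# sets with regex leaf matching, the Fisher oracle enumerates the
# hypergeometric support from log-binomials, the reachability oracle walks
# parent edges iteratively, and the headline oracle enumerates root paths
# recursively from the raw edge table.

# --- boolean query oracle (set semantics, regex leaves) --------------------

oracle_leaf_matches <- function(record, node) {
  if (!is.null(node$field)) {
    if (node$field == "PT") {
      types <- tolower(trimws(strsplit(record$publication_types, ";")[[1]]))
      return(if (node$wildcard) any(startsWith(types, node$token))
             else node$token %in% types)
    }
    if (node$field == "PL") {
      cn <- tolower(trimws(record$country))
      return(if (node$wildcard) startsWith(cn, node$token)
             else cn == node$token)
    }
    stop("oracle: unknown field")
  }
  txt <- tolower(record$text)
  rx <- if (node$wildcard)
    paste0("(^|[^a-z0-9])", node$token)
  else
    paste0("(^|[^a-z0-9])", node$token, "($|[^a-z0-9])")
  grepl(rx, txt)
}

oracle_match_set <- function(corpus, node) {
  idx <- seq_len(nrow(corpus))
  switch(node$kind,
    all = idx,
    term = idx[vapply(idx, function(i)
      oracle_leaf_matches(corpus[i, , drop = FALSE], node), logical(1))],
    and = intersect(oracle_match_set(corpus, node$children[[1]]),
                    oracle_match_set(corpus, node$children[[2]])),
    or = union(oracle_match_set(corpus, node$children[[1]]),
               oracle_match_set(corpus, node$children[[2]])),
    not = setdiff(oracle_match_set(corpus, node$children[[1]]),
                  oracle_match_set(corpus, node$children[[2]])),
    stop("oracle: unknown node kind"))
}

# random corpora and random query trees for property tests
random_corpus <- function(n, vocab) {
  data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    year = sample(1995:2020, n, replace = TRUE),
    country = sample(c("Germany", "France", "Japan"), n, replace = TRUE),
    publication_types = sample(c("Journal Article", "Journal Article;Review"),
                               n, replace = TRUE),
    text = vapply(seq_len(n), function(i)
      paste(sample(vocab, sample(3:8, 1), replace = TRUE), collapse = " "),
      character(1)),
    cumulative_citations = sample(0:50, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_query_string <- function(vocab, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    tok <- sample(vocab, 1)
    if (stats::runif(1) < 0.25) tok <- paste0(substr(tok, 1, 3), "*")
    if (stats::runif(1) < 0.15) tok <- "review[PT]"
    return(tok)
  }
  op <- sample(c("AND", "OR", "NOT"), 1)
  sprintf("(%s %s %s)", random_query_string(vocab, depth - 1), op,
          random_query_string(vocab, depth - 1))
}

# --- Fisher two-sided oracle ----------------------------------------------

oracle_fisher_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  logp <- function(x) lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  ps <- exp(vapply(lo:hi, logp, numeric(1)))
  pobs <- exp(logp(a))
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# --- Pearson chi-square oracle --------------------------------------------

oracle_chi_square <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# --- DAG oracles -----------------------------------------------------------

# ancestors of each term by iterative expansion over the edge table
oracle_ancestors <- function(edges, term) {
  anc <- character(); frontier <- term
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    parents <- setdiff(parents, anc)
    anc <- c(anc, parents)
    frontier <- parents
  }
  anc
}

# propagated gene set of a term = direct genes of the term plus of every
# term having it among its ancestors
oracle_propagated <- function(edges, direct, term, all_terms) {
  below <- all_terms[vapply(all_terms, function(t)
    term %in% c(t, oracle_ancestors(edges, t)), logical(1))]
  unique(unlist(direct[below]))
}

# all simple paths (as vectors of term ids) from `from` up to any root
oracle_root_paths <- function(edges, from) {
  parents_of <- function(t) edges$parent[edges$child == t]
  rec <- function(t) {
    ps <- parents_of(t)
    if (length(ps) == 0) return(list(t))
    out <- list()
    for (p in ps) for (tail in rec(p)) out <- c(out, list(c(t, tail)))
    out
  }
  rec(from)
}
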