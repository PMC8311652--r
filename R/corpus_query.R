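#' @name corpus_query
#' @title Boolean literature queries over a local publication corpus
#'
#' @description
#' A small query language with PubMed-flavoured semantics: whole-token
#' case-insensitive term matching on the title+abstract text, trailing-`*`
#' prefix wildcards, field tags `[PT]` (publication type) and `[PL]`
#' (country of the first-author affiliation), and boolean operators with
#' precedence `NOT > AND > OR` where `A NOT B` means matches of A without
#' the matches of B. An empty query string denotes match-all.
NULL

query_fields <- c("PT", "PL")

# --- tokenizer -------------------------------------------------------------

# Splits a query string into parentheses, operator words and term tokens.
# Double quotes (straight or typographic) are stripped: the language has no
# phrase semantics, mirroring how stray quotes in a pasted search string are
# tolerated by search engines.
tokenize_query <- function(text) {
  text <- gsub("[\"“”]", "", text)
  pat <- "\\(|\\)|\\[[A-Za-z]+\\]|[A-Za-z0-9*'-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(data.frame(token = character(), pos = integer()))
  data.frame(token = regmatches(text, gregexpr(pat, text))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

query_syntax_error <- function(msg, pos) {
  abort2(sprintf("query syntax error at position %d: %s", pos, msg),
         "query_syntax_error")
}

# --- parser ----------------------------------------------------------------

#' Parse a boolean query string
#'
#' Recursive-descent parser honouring parentheses, precedence
#' `NOT > AND > OR`, left associativity, trailing-`*` wildcards and field
#' tags bound to the immediately preceding term.
#'
#' @param text Query string; the empty (or all-whitespace) string parses to
#'   an explicit match-all node.
#' @return A `query_node`: a nested list with `kind` in
#'   `c("all", "term", "and", "or", "not")`; term nodes carry `token`,
#'   `wildcard` and optional `field`.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- tokenize_query(text)
  if (nrow(toks) == 0)
    return(structure(list(kind = "all"), class = "query_node"))
  i <- 1L
  peek <- function() if (i <= nrow(toks)) toks$token[i] else NA_character_
  pos <- function() if (i <= nrow(toks)) toks$pos[i] else nchar(text) + 1L
  advance <- function() { i <<- i + 1L }

  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && peek() == "OR") {
      advance()
      rhs <- parse_and()
      node <- list(kind = "or", children = list(node, rhs))
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.na(peek()) && peek() == "AND") {
      advance()
      rhs <- parse_not()
      node <- list(kind = "and", children = list(node, rhs))
    }
    node
  }
  parse_not <- function() {
    node <- parse_unary()
    while (!is.na(peek()) && peek() == "NOT") {
      advance()
      rhs <- parse_unary()
      node <- list(kind = "not", children = list(node, rhs))
    }
    node
  }
  parse_unary <- function() {
    tk <- peek()
    if (is.na(tk)) query_syntax_error("dangling operator", pos())
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        query_syntax_error("unbalanced parentheses: expected ')'", pos())
      advance()
      return(node)
    }
    if (tk %in% c(")", "AND", "OR", "NOT"))
      query_syntax_error(sprintf("unexpected '%s'", tk), pos())
    if (grepl("^\\[[A-Za-z]+\\]$", tk))
      query_syntax_error("field tag without a preceding term", pos())
    advance()
    wildcard <- endsWith(tk, "*")
    token <- tolower(sub("\\*+$", "", tk))
    if (!nzchar(token)) query_syntax_error("empty term", pos())
    field <- NULL
    if (!is.na(peek()) && grepl("^\\[[A-Za-z]+\\]$", peek())) {
      field <- toupper(gsub("\\[|\\]", "", peek()))
      advance()
    }
    list(kind = "term", token = token, wildcard = wildcard, field = field)
  }

  node <- parse_or()
  if (!is.na(peek()))
    query_syntax_error(sprintf("unexpected trailing '%s'", peek()), pos())
  structure(node, class = "query_node")
}

#' @export
format.query_node <- function(x, ...) {
  rec <- function(n) switch(n$kind,
    all = "<ALL>",
    term = paste0(n$token, if (isTRUE(n$wildcard)) "*",
                  if (!is.null(n$field)) paste0("[", n$field, "]")),
    paste0("(", rec(n$children[[1]]), " ", toupper(n$kind), " ",
           rec(n$children[[2]]), ")"))
  rec(x)
}

#' @export
print.query_node <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# --- matching --------------------------------------------------------------

#' Tokenize free text for term matching
#'
#' Lowercases and splits on any non-alphanumeric character.
#'
#' @param text Character vector.
#' @return List of character vectors of tokens, one per input element.
#' @export
tokenize_text <- function(text) {
  strsplit(tolower(text), "[^a-z0-9]+")
}

match_tokens <- function(tokens, term, wildcard) {
  tokens <- tokens[nzchar(tokens)]
  if (wildcard) any(startsWith(tokens, term)) else any(tokens == term)
}

#' Evaluate a query against one publication record
#'
#' @param record List or one-row data frame with fields `text`,
#'   `publication_types` (character vector or `;`-separated string) and
#'   `country`.
#' @param query A `query_node` from [parse_query()] (or a query string).
#' @return Logical scalar.
#' @export
match_record <- function(record, query) {
  if (is.character(query)) query <- parse_query(query)
  types <- record$publication_types
  if (is.list(types)) types <- types[[1]]
  if (length(types) == 1 && grepl(";", types, fixed = TRUE))
    types <- strsplit(types, ";", fixed = TRUE)[[1]]
  types <- tolower(trimws(types))
  country <- tolower(trimws(record$country %||% ""))
  tokens <- tokenize_text(record$text %||% "")[[1]]
  rec <- function(n) switch(n$kind,
    all = TRUE,
    term = {
      if (is.null(n$field)) {
        match_tokens(tokens, n$token, n$wildcard)
      } else if (n$field == "PT") {
        if (n$wildcard) any(startsWith(types, n$token)) else n$token %in% types
      } else if (n$field == "PL") {
        if (n$wildcard) startsWith(country, n$token) else country == n$token
      } else {
        abort2(sprintf("unknown field tag [%s]; supported: %s", n$field,
                       paste(query_fields, collapse = ", ")),
               "query_field_error")
      }
    },
    and = rec(n$children[[1]]) && rec(n$children[[2]]),
    or = rec(n$children[[1]]) || rec(n$children[[2]]),
    not = rec(n$children[[1]]) && !rec(n$children[[2]]),
    abort2(sprintf("unknown query node kind '%s'", n$kind), "query_eval_error"))
  rec(query)
}

#' Filter a publication corpus with a boolean query
#'
#' @param corpus Data frame of publication records with columns `record_id`,
#'   `year`, `country`, `publication_types`, `text`, `cumulative_citations`
#'   and optionally `included` (a curation flag; see `honor_included`).
#' @param query Query string or `query_node`.
#' @param honor_included If `TRUE` and the corpus has an `included` column,
#'   records flagged `FALSE` are removed from the matches (stand-in for the
#'   manual inclusion screening applied after the database search).
#' @return List with `matches` (subset of `corpus`, input order preserved)
#'   and `year_counts` (named integer vector over the matched years).
#' @export
filter_corpus <- function(corpus, query, honor_included = FALSE) {
  if (is.character(query)) query <- parse_query(query)
  hit <- vapply(seq_len(nrow(corpus)), function(i)
    match_record(corpus[i, , drop = FALSE], query), logical(1))
  if (honor_included && "included" %in% names(corpus))
    hit <- hit & (corpus$included %in% c(TRUE, NA))
  matches <- corpus[hit, , drop = FALSE]
  year_counts <- if (nrow(matches)) {
    tab <- table(matches$year)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  list(matches = matches, year_counts = year_counts)
}

#' The default epigenetics-and-drugs search string
#'
#' The boolean search string used to retrieve original (non-review) reports
#' on epigenetic drug effects, honoured literally including its historical
#' spelling variants. The circulating form of this string is short one
#' closing parenthesis (search engines silently repair this); the balanced
#' repair is returned so it parses under the strict grammar.
#'
#' @return Character scalar.
#' @export
epigenetics_drug_query <- function() {
  paste0(
    "(epigen* AND (histon* OR chromatin* OR DNA) AND ",
    "(modificat* OR alterat* OR modulat* OR changes OR changing) AND ",
    "(methylase OR demethylase OR acethylase OR deacetylase OR ubiquinase ",
    "OR deubiquinase OR phosphorylase OR dephosphorylase OR sumoylase) AND ",
    "((drug OR pharmaceut*) NOT (review[PT])))")
}
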