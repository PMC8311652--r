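#' Closed vocabulary of epigenetic enzyme actions
#'
#' The fourteen reaction classes covered by the registry: two acting on the
#' DNA itself (methylation, demethylation) and twelve acting on histones
#' (addition and removal of methyl, acetyl, ubiquitin, phosphoryl and
#' ADP-ribosyl marks, plus citrullination and biotinylation).
#'
#' @format Character vector of length 14.
#' @export
enzyme_actions <- c(
  "DNA methylation", "DNA demethylation",
  "histone methylation", "histone demethylation",
  "histone acetylation", "histone deacetylation",
  "histone ubiquitination", "histone deubiquitination",
  "histone phosphorylation", "histone dephosphorylation",
  "histone ADP-ribosylation", "histone de-ADP-ribosylation",
  "histone citrullination", "histone biotinylation"
)

# Canonicalize an action label case-insensitively against the closed
# vocabulary; returns NA for labels outside it.
canonical_action <- function(label) {
  idx <- match(tolower(trimws(label)), tolower(enzyme_actions))
  enzyme_actions[idx]
}

new_enzyme_registry <- function(records, source_label = "unknown") {
  stopifnot(is.data.frame(records))
  structure(list(records = records, source_label = source_label),
            class = "enzyme_registry")
}

#' @export
print.enzyme_registry <- function(x, ...) {
  cat(sprintf("<enzyme_registry> %d enzymes (source: %s)\n",
              nrow(x$records), x$source_label))
  invisible(x)
}

#' @export
length.enzyme_registry <- function(x) nrow(x$records)

empty_registry_records <- function() {
  data.frame(gene_symbol = character(), gene_name = character(),
             ncbi_gene_id = integer(), uniprot_id = character(),
             enzyme_action = character(), stringsAsFactors = FALSE)
}

validate_registry_records <- function(records) {
  if (any(!nzchar(records$gene_symbol)))
    abort2("gene_symbol must be non-empty for every record", "registry_invalid")
  bad <- !records$enzyme_action %in% enzyme_actions
  if (any(bad))
    abort2(sprintf("unknown enzyme action label(s): %s",
                   paste(unique(records$enzyme_action[bad]), collapse = ", ")),
           "registry_invalid")
  if (anyDuplicated(records$gene_symbol))
    abort2("duplicate gene symbols in registry", "registry_invalid")
  if (anyDuplicated(records$ncbi_gene_id[!is.na(records$ncbi_gene_id)]))
    abort2("duplicate NCBI gene ids in registry", "registry_invalid")
  invisible(records)
}

#' Parse an enzyme-registry XML file
#'
#' Reads the documented registry dialect: a `<registry>` root with one
#' `<enzyme>` element per record, carrying child elements
#' `<gene_symbol>`, `<gene_name>`, `<ncbi_gene_id>`, `<uniprot_id>`
#' (optional) and `<subclass>` (the enzyme action; mandatory).
#' Duplicated gene symbols are collapsed to their first occurrence with a
#' warning; records lacking a subclass or carrying an action outside the
#' closed vocabulary are skipped and collected in the parse report.
#'
#' @param source Path to a registry XML file (or anything [xml2::read_xml()]
#'   accepts).
#' @param source_label Provenance string stored on the registry.
#' @return An `enzyme_registry` with attributes `n_parsed`, `n_dropped_duplicate`
#'   and `record_errors` (character vector of per-record problems).
#' @export
parse_enzyme_registry <- function(source, source_label = "registry-xml") {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    abort2(paste0("malformed registry XML: ", conditionMessage(e)), "xml_parse_error"))
  nodes <- xml2::xml_find_all(doc, "/registry/enzyme")
  errors <- character()
  rows <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    get1 <- function(tag) {
      v <- xml2::xml_find_first(nd, tag)
      if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
    }
    subclass <- get1("subclass")
    symbol <- get1("gene_symbol")
    if (is.na(subclass) || !nzchar(subclass)) {
      errors <- c(errors, sprintf("enzyme #%d (%s): missing mandatory subclass",
                                  i, symbol %||% "?"))
      next
    }
    action <- canonical_action(subclass)
    if (is.na(action)) {
      errors <- c(errors, sprintf("enzyme #%d (%s): unknown action '%s'",
                                  i, symbol, subclass))
      next
    }
    rows[[i]] <- data.frame(
      gene_symbol = symbol,
      gene_name = get1("gene_name"),
      ncbi_gene_id = suppressWarnings(as.integer(get1("ncbi_gene_id"))),
      uniprot_id = get1("uniprot_id"),
      enzyme_action = action,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, c(list(empty_registry_records()), rows))
  dup <- duplicated(records$gene_symbol)
  n_dropped <- sum(dup)
  if (n_dropped > 0) {
    warn2(sprintf("dropped %d duplicate enzyme record(s): %s", n_dropped,
                  paste(unique(records$gene_symbol[dup]), collapse = ", ")),
          "registry_duplicates")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  validate_registry_records(records)
  reg <- new_enzyme_registry(records, source_label)
  attr(reg, "n_parsed") <- nrow(records)
  attr(reg, "n_dropped_duplicate") <- n_dropped
  attr(reg, "record_errors") <- errors
  reg
}

#' Serialize a registry to the XML dialect
#'
#' Inverse of [parse_enzyme_registry()]; emits deterministic bytes so a
#' round trip reproduces the file exactly.
#'
#' @param registry An `enzyme_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enzyme_registry_xml <- function(registry, path) {
  r <- registry$records
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<registry>")
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, "  <enzyme>",
      sprintf("    <gene_symbol>%s</gene_symbol>", xml_escape(r$gene_symbol[i])),
      sprintf("    <gene_name>%s</gene_name>", xml_escape(r$gene_name[i])),
      sprintf("    <ncbi_gene_id>%s</ncbi_gene_id>", r$ncbi_gene_id[i]),
      if (!is.na(r$uniprot_id[i]) && nzchar(r$uniprot_id[i]))
        sprintf("    <uniprot_id>%s</uniprot_id>", xml_escape(r$uniprot_id[i])),
      sprintf("    <subclass>%s</subclass>", xml_escape(r$enzyme_action[i])),
      "  </enzyme>")
  }
  lines <- c(lines, "</registry>")
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged registry of drug-interacting epigenetic enzymes
#'
#' Returns the curated registry of 68 human enzymes catalysing classical
#' epigenetic reactions for which interactions with approved or
#' investigational drugs are known, shipped as a TSV fixture with columns
#' `enzyme_action`, `gene_name`, `gene_symbol`, `ncbi_gene_id`.
#'
#' @param path Optional override of the packaged TSV.
#' @return An `enzyme_registry` with 68 records.
#' @export
load_packaged_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "epigenetic_enzymes.tsv",
                                package = "epidrugminer", mustWork = TRUE)
  df <- read_tsv_file(path)
  records <- data.frame(
    gene_symbol = df$gene_symbol,
    gene_name = df$gene_name,
    ncbi_gene_id = as.integer(df$ncbi_gene_id),
    uniprot_id = NA_character_,
    enzyme_action = vapply(df$enzyme_action, canonical_action, character(1),
                           USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  validate_registry_records(records)
  new_enzyme_registry(records, source_label = "packaged")
}

#' Classify an enzyme action by its substrate
#'
#' DNA-directed actions act on cytosines of the DNA itself; all other
#' classical epigenetic reactions modify histone tails.
#'
#' @param action_label Action label from the closed vocabulary (vectorised).
#' @return `"DNA"` or `"histone"` per element.
#' @export
classify_substrate <- function(action_label) {
  canon <- canonical_action(action_label)
  if (anyNA(canon))
    abort2(sprintf(
      "unknown enzyme action label(s): %s; accepted labels: %s",
      paste(unique(action_label[is.na(canon)]), collapse = ", "),
      paste(enzyme_actions, collapse = ", ")), "vocabulary_error")
  ifelse(startsWith(canon, "DNA"), "DNA", "histone")
}

#' Summarise a registry
#'
#' @param registry An `enzyme_registry`.
#' @return List with `n_unique_enzymes`, `action_counts` (named integer over
#'   all 14 actions, zero-filled) and `substrate_counts`.
#' @export
registry_summary <- function(registry) {
  r <- registry$records
  counts <- table(factor(r$enzyme_action, levels = enzyme_actions))
  action_counts <- stats::setNames(as.integer(counts), names(counts))
  substrate <- if (nrow(r)) classify_substrate(r$enzyme_action) else character()
  substrate_counts <- stats::setNames(
    as.integer(table(factor(substrate, levels = c("DNA", "histone")))),
    c("DNA", "histone"))
  list(n_unique_enzymes = length(unique(r$gene_symbol)),
       action_counts = action_counts,
       substrate_counts = substrate_counts)
}

#' Validate gene symbols and NCBI ids against a reference symbol table
#'
#' Offline stand-in for a nomenclature-service lookup: each record's
#' (gene_symbol, ncbi_gene_id) pair is checked against a packaged reference
#' table (by default the packaged registry itself).
#'
#' @param registry An `enzyme_registry`.
#' @param reference Data frame with `gene_symbol` and `ncbi_gene_id` columns;
#'   defaults to the packaged registry fixture.
#' @return Data frame of mismatching records (zero rows when all verify).
#' @export
verify_gene_identifiers <- function(registry, reference = NULL) {
  ref <- reference %||% load_packaged_registry()$records
  r <- registry$records
  key <- paste(r$gene_symbol, r$ncbi_gene_id)
  ok <- key %in% paste(ref$gene_symbol, ref$ncbi_gene_id)
  out <- r[!ok, c("gene_symbol", "ncbi_gene_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}
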