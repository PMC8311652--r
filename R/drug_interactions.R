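#' @name drug_interactions
#' @title Drug-database mining and the drug-by-enzyme interaction matrix
#'
#' @description
#' Parses drug records from a minimal DrugBank-v5-style XML dialect
#' (per-drug development groups, categories and targets with UniProt id and
#' organism), filters to development groups of therapeutic relevance
#' (approved/investigational) and human targets, and crosses the remaining
#' targets with an epigenetic-enzyme registry to produce a binary
#' drug-by-enzyme incidence matrix with marginal statistics.
NULL

drug_groups <- c("approved", "investigational", "experimental", "illicit",
                 "nutraceutical", "vet_approved", "withdrawn")

#' Parse a drug-database XML file
#'
#' Dialect: `<drugbank>` root; per drug a `<drug>` element with children
#' `<drugbank-id>`, `<name>`, `<groups><group>...`,
#' `<categories><category>...`, and
#' `<targets><target><polypeptide uniprot-id="..."><organism>...` (the
#' polypeptide may also carry `gene-symbol` and `ncbi-gene-id` attributes).
#'
#' @param source Path or connection readable by [xml2::read_xml()].
#' @return List of drug records (`drug_id`, `name`, `groups`, `categories`,
#'   `targets` data frame) of class `drug_collection`, with attributes
#'   `group_counts` and `n_skipped` (drugs lacking an id).
#' @export
parse_drug_database <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    abort2(paste0("malformed drug XML: ", conditionMessage(e)), "xml_parse_error"))
  nodes <- xml2::xml_find_all(doc, "/drugbank/drug")
  n_skipped <- 0L
  drugs <- list()
  for (nd in nodes) {
    id <- xml2::xml_text(xml2::xml_find_first(nd, "drugbank-id"))
    if (is.na(id) || !nzchar(id)) { n_skipped <- n_skipped + 1L; next }
    tnodes <- xml2::xml_find_all(nd, "targets/target/polypeptide")
    targets <- data.frame(
      uniprot_id = xml2::xml_attr(tnodes, "uniprot-id"),
      organism = vapply(tnodes, function(p)
        xml2::xml_text(xml2::xml_find_first(p, "organism")), character(1)),
      gene_symbol = xml2::xml_attr(tnodes, "gene-symbol"),
      stringsAsFactors = FALSE)
    drugs[[length(drugs) + 1L]] <- list(
      drug_id = id,
      name = xml2::xml_text(xml2::xml_find_first(nd, "name")),
      groups = xml2::xml_text(xml2::xml_find_all(nd, "groups/group")),
      categories = unique(xml2::xml_text(xml2::xml_find_all(nd, "categories/category"))),
      targets = targets)
  }
  if (n_skipped > 0)
    warn2(sprintf("skipped %d drug element(s) without a drugbank-id", n_skipped),
          "drug_skipped")
  group_counts <- table(factor(unlist(lapply(drugs, `[[`, "groups")),
                               levels = drug_groups))
  structure(drugs, class = "drug_collection",
            group_counts = stats::setNames(as.integer(group_counts),
                                           names(group_counts)),
            n_skipped = n_skipped)
}

#' Serialize a drug collection to the XML dialect
#'
#' Deterministic inverse of [parse_drug_database()].
#'
#' @param drugs A `drug_collection` (or plain list of drug records).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_database_xml <- function(drugs, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<drugbank>")
  for (d in drugs) {
    lines <- c(lines, "  <drug>",
      sprintf("    <drugbank-id>%s</drugbank-id>", xml_escape(d$drug_id)),
      sprintf("    <name>%s</name>", xml_escape(d$name)),
      "    <groups>",
      sprintf("      <group>%s</group>", xml_escape(d$groups)),
      "    </groups>",
      "    <categories>",
      if (length(d$categories))
        sprintf("      <category>%s</category>", xml_escape(d$categories)),
      "    </categories>",
      "    <targets>")
    tg <- d$targets
    for (j in seq_len(NROW(tg))) {
      gs <- tg$gene_symbol[j]
      attr_gs <- if (!is.na(gs) && nzchar(gs))
        sprintf(' gene-symbol="%s"', xml_escape(gs)) else ""
      lines <- c(lines, "      <target>",
        sprintf('        <polypeptide uniprot-id="%s"%s>',
                xml_escape(tg$uniprot_id[j]), attr_gs),
        sprintf("          <organism>%s</organism>", xml_escape(tg$organism[j])),
        "        </polypeptide>",
        "      </target>")
    }
    lines <- c(lines, "    </targets>", "  </drug>")
  }
  lines <- c(lines, "</drugbank>")
  writeLines(lines, path)
  invisible(path)
}

#' Filter drugs by development group and target organism
#'
#' Keeps drugs with at least one allowed development group and restricts
#' each kept drug's targets to the configured organism. Drugs left without
#' targets are retained (they simply contribute no interactions).
#'
#' @param drugs A `drug_collection`.
#' @param allowed_groups Development groups to keep (default approved and
#'   investigational, the groups with likely therapeutic relevance).
#' @param human_only Restrict targets to `organism_label`?
#' @param organism_label Organism string for the target filter,
#'   case-insensitively matched (default `"Humans"`, the DrugBank label).
#' @return Filtered `drug_collection`.
#' @export
select_drugs <- function(drugs,
                         allowed_groups = c("approved", "investigational"),
                         human_only = TRUE, organism_label = "Humans") {
  kept <- Filter(function(d) any(d$groups %in% allowed_groups), drugs)
  if (human_only) {
    kept <- lapply(kept, function(d) {
      tg <- d$targets
      d$targets <- tg[tolower(trimws(tg$organism)) ==
                        tolower(organism_label), , drop = FALSE]
      rownames(d$targets) <- NULL
      d
    })
  }
  structure(kept, class = "drug_collection")
}

#' Build the binary drug-by-enzyme interaction matrix
#'
#' A cell (drug, enzyme) is 1 when the drug lists a target whose UniProt id
#' maps to the enzyme's gene symbol. Targets without a mapping-table row
#' fall back to their own `gene_symbol` field when present; targets with
#' neither are dropped and counted. Drugs and enzymes without any
#' interaction are excluded from the axes; both axes are sorted
#' lexicographically for deterministic serialization.
#'
#' @param drugs Filtered `drug_collection` (see [select_drugs()]).
#' @param registry An `enzyme_registry`.
#' @param id_map Optional data frame mapping `uniprot_id` to `gene_symbol`.
#' @return An `interaction_matrix`: list with `matrix` (0/1 integer matrix,
#'   drugs in rows), `drug_marginals`, `enzyme_marginals`, `total`, and
#'   `n_unmapped_targets`.
#' @export
build_interaction_matrix <- function(drugs, registry, id_map = NULL) {
  if (length(registry) == 0)
    abort2("cannot match against an empty enzyme registry", "empty_registry")
  enzymes <- registry$records$gene_symbol
  map <- if (!is.null(id_map))
    stats::setNames(id_map$gene_symbol, id_map$uniprot_id) else character()
  n_unmapped <- 0L
  pairs <- list()
  for (d in drugs) {
    tg <- d$targets
    if (NROW(tg) == 0) next
    genes <- unname(map[tg$uniprot_id])
    fallback <- is.na(genes)
    genes[fallback] <- tg$gene_symbol[fallback]
    unmapped <- is.na(genes) | !nzchar(genes)
    n_unmapped <- n_unmapped + sum(unmapped)
    hit <- unique(genes[!unmapped & genes %in% enzymes])
    if (length(hit))
      pairs[[length(pairs) + 1L]] <- data.frame(drug = d$name, enzyme = hit,
                                                stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) {
    m <- matrix(0L, 0, 0)
  } else {
    inc <- unique(do.call(rbind, pairs))
    dn <- sort(unique(inc$drug)); en <- sort(unique(inc$enzyme))
    m <- matrix(0L, length(dn), length(en), dimnames = list(dn, en))
    m[cbind(match(inc$drug, dn), match(inc$enzyme, en))] <- 1L
  }
  structure(list(matrix = m,
                 drug_marginals = rowSums(m),
                 enzyme_marginals = colSums(m),
                 total = sum(m),
                 n_unmapped_targets = n_unmapped),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d drugs x %d enzymes, %d interactions\n",
              nrow(x$matrix), ncol(x$matrix), x$total))
  invisible(x)
}

#' Histogram of drug categories
#'
#' Counts distinct drugs per category label; categories carried by fewer
#' than `min_count` drugs are suppressed.
#'
#' @param drugs A `drug_collection`.
#' @param min_count Minimum drugs per reported category (default 5).
#' @return Data frame (`category`, `n_drugs`) sorted by decreasing count
#'   then category.
#' @export
category_histogram <- function(drugs, min_count = 5) {
  cats <- unlist(lapply(drugs, function(d) unique(d$categories)))
  if (length(cats) == 0)
    return(data.frame(category = character(), n_drugs = integer()))
  tab <- table(cats)
  out <- data.frame(category = names(tab), n_drugs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n_drugs >= min_count, , drop = FALSE]
  out <- out[order(-out$n_drugs, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param yates Apply the continuity correction? Default `FALSE`
#'   (plain Pearson form).
#' @return List with `chi_square`, `df` (= 1) and `p_value`.
#' @export
two_by_two_chi_square <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort2("table must be 2x2", "domain_error")
  if (any(tab < 0)) abort2("counts must be non-negative", "domain_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort2("zero row or column margin", "zero_margin")
  # small expected counts only trigger the usual approximation caveat
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Share of a part in a whole, as a display percentage
#'
#' @param part,whole Non-negative counts, `whole > 0`.
#' @param digits Decimal places for display (default 2).
#' @return Numeric percentage rounded to `digits`.
#' @export
percentage_share <- function(part, whole, digits = 2) {
  if (whole <= 0) abort2("whole must be positive", "domain_error")
  round(100 * part / whole, digits)
}

#' Coverage statistics of the interaction analysis
#'
#' @param drugs Filtered `drug_collection`.
#' @param matrix An `interaction_matrix`.
#' @param registry The `enzyme_registry` used for matching.
#' @param n_all_drugs Optional size of the full drug universe (for the
#'   drug-share percentage).
#' @param n_all_human_targets Optional size of the human target universe
#'   (for the target-share percentage).
#' @return List of exact counts plus two-decimal display percentages where
#'   the corresponding universe size was supplied.
#' @export
coverage_statistics <- function(drugs, matrix, registry,
                                n_all_drugs = NULL, n_all_human_targets = NULL) {
  out <- list(
    n_drugs_considered = length(drugs),
    n_interacting_drugs = nrow(matrix$matrix),
    n_interacting_enzymes = ncol(matrix$matrix),
    n_registry_enzymes = length(registry),
    total_interactions = matrix$total)
  if (!is.null(n_all_drugs))
    out$pct_interacting_drugs <-
      percentage_share(out$n_interacting_drugs, n_all_drugs)
  if (!is.null(n_all_human_targets))
    out$pct_epigenetic_targets <-
      percentage_share(out$n_interacting_enzymes, n_all_human_targets)
  out
}
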