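# Small in-code fixtures used by the worked examples and the acceptance
# checks; all are constructed programmatically so the package ships no
# binary data.

#' Epigenetic targets of fostamatinib
#'
#' The 20 genes encoding epigenetic enzymes among the targets of the
#' SYK-inhibitor fostamatinib, the drug with the most epigenetic-enzyme
#' interactions in the analysis. All 20 act on histones (kinases of the
#' histone-phosphorylation class).
#'
#' @return Character vector of 20 gene symbols.
#' @export
fostamatinib_epigenetic_targets <- function() {
  c("AURKA", "AURKB", "AURKC", "CDK17", "CHEK1", "DAPK3", "FYN", "GSK3B",
    "JAK2", "LIMK2", "MAP3K12", "MAP3K20", "NEK9", "PAK1", "PAK2", "PKN1",
    "PRKAA1", "RPS6KA3", "STK10", "TLK1")
}

#' Build a fostamatinib drug record with decoy targets
#'
#' Constructs a synthetic `drug_collection` of one approved drug named
#' "Fostamatinib" whose human targets are the 20 epigenetic gene symbols
#' plus `n_decoys` decoy symbols guaranteed absent from any registry
#' (prefix `ZZDECOY`), emulating the drug's long non-epigenetic target list.
#'
#' @param n_decoys Number of decoy targets to append (default 30).
#' @return A `drug_collection` of length 1.
#' @export
fostamatinib_record <- function(n_decoys = 30) {
  genes <- c(fostamatinib_epigenetic_targets(),
             sprintf("ZZDECOY%03d", seq_len(n_decoys)))
  targets <- data.frame(
    uniprot_id = sprintf("UPF%04d", seq_along(genes)),
    organism = "Humans",
    gene_symbol = genes,
    stringsAsFactors = FALSE)
  structure(list(list(drug_id = "DB12010", name = "Fostamatinib",
                      groups = c("approved", "investigational"),
                      categories = c("Protein Kinase Inhibitors"),
                      targets = targets)),
            class = "drug_collection")
}
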