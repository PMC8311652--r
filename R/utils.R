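#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Plain-text I/O only: TSV with
# tab separation and no quoting (gene names contain commas but no tabs).

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# XML text escaping for the deterministic writers (generators must be
# byte-reproducible, so markup is emitted as text rather than via a DOM).
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

# stop()/warning() wrappers carrying a condition class so callers and tests
# can distinguish contract violations from incidental errors.
abort2 <- function(msg, class) {
  stop(structure(class = c(class, "epidrugminer_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn2 <- function(msg, class) {
  warning(structure(class = c(class, "epidrugminer_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
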