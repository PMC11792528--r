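# internal IO + small helpers shared across modules

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA"), ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

# C-locale sort so representative choice / row order never depends on locale
.radix_sort <- function(x) sort(x, method = "radix")

.radix_order <- function(...) order(..., method = "radix")

# 20 standard residues plus X (unknown); peptide sequences must be plain
.AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

.is_aa <- function(x) grepl(.AA_REGEX, x)

.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

.comma_list <- function(x, max = 5L) {
  x <- unique(x)
  extra <- if (length(x) > max) sprintf(" (and %d more)", length(x) - max) else ""
  paste0(paste(utils::head(x, max), collapse = ", "), extra)
}
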