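# Internal helpers shared across modules.

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.trim <- function(x) sub("^\\s+", "", sub("\\s+$", "", x))

# Deterministic key for a subunit set (order- and duplication-insensitive).
.subunit_key <- function(tokens) paste(sort(unique(tokens)), collapse = ";")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
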