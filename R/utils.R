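# internal helpers shared across modules

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dualprom <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dualprom_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# safe TSV writers: never mangle strings containing commas/slashes/quotes
write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}
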