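`%||%` <- function(x, y) if (is.null(x)) y else x

.msg <- function(...) message(sprintf(...))

.assertScalarChar <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  invisible(x)
}

.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# wrap a sequence at `width` columns without a trailing blank line
.wrapSeq <- function(s, width = 60L) {
  n <- nchar(s)
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

.writeFasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), .wrapSeq(as.character(seqs[[i]]), width)), con)
  invisible(path)
}
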