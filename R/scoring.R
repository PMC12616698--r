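#' Read a substitution matrix in NCBI plain-text format
#'
#' Parses the whitespace-separated matrix layout used by NCBI tools (comment
#' lines starting with `#`, a header row of residue letters, one labelled row
#' per residue).
#'
#' @param path path to the matrix file
#' @return an integer matrix with residue dimnames
#' @seealso [scoringScheme()]; BLOSUM62 and BLOSUM45 are shipped under
#'   `system.file("extdata", package = "resMiner")`
#' @export
readScoreMatrix <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  header <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(ln[-1]), "\\s+")
  lab <- vapply(rows, `[`, "", 1L)
  m <- t(vapply(rows, function(r) as.integer(r[-1]),
                integer(length(header))))
  dimnames(m) <- list(lab, header)
  if (!identical(rownames(m), colnames(m)))
    stop("malformed matrix file: row and column labels differ")
  m
}

#' Construct a scoring scheme for protein local alignment
#'
#' Loads one of the shipped substitution matrices, restricts it to the 20
#' amino acids plus `X`, and forces `X` to score 0 against every residue
#' (ambiguous translation products neither reward nor penalise a column).
#'
#' @param matrixName "BLOSUM62" (default) or "BLOSUM45"
#' @param gapOpen gap opening penalty; a gap of length k costs
#'   `gapOpen + k * gapExtend` (default 11)
#' @param gapExtend gap extension penalty (default 1)
#' @return a [ScoringScheme-class]
#' @examples
#' sch <- scoringScheme()
#' sch@matrix["A", "A"]   # 4
#' @export
scoringScheme <- function(matrixName = c("BLOSUM62", "BLOSUM45"),
                          gapOpen = 11L, gapExtend = 1L) {
  matrixName <- match.arg(matrixName)
  path <- system.file("extdata", paste0(matrixName, ".txt"),
                      package = "resMiner", mustWork = TRUE)
  m <- readScoreMatrix(path)
  keep <- strsplit(.AA_ALPHABET, "")[[1]]
  m <- m[keep, keep]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  new("ScoringScheme", matrixName = matrixName, matrix = m,
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend))
}
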