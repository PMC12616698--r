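# sequence input coercion: AAStringSet / AAString / character all accepted
.asProtChar <- function(x) {
  if (is(x, "AAStringSet")) return(setNames(as.character(x), names(x)))
  if (is(x, "AAString")) return(as.character(x))
  if (is.character(x)) return(x)
  stop("expected character, AAString or AAStringSet")
}

.hitFromRow <- function(queryId, targetId, row, qlen, tlen) {
  new("AlignmentHit",
      queryId = queryId, targetId = targetId,
      score = as.integer(row$score),
      percentIdentity = 100 * row$matches / row$columns,
      queryCoverage = (row$qend - row$qstart + 1) / qlen,
      targetCoverage = (row$tend - row$tstart + 1) / tlen,
      queryRange = as.integer(c(row$qstart, row$qend)),
      targetRange = as.integer(c(row$tstart, row$tend)))
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under affine gap penalties (Gotoh algorithm) with
#' the matrix and penalties of `scheme`. The traceback is deterministic:
#' among equally scoring end cells the smallest row then column wins, and
#' within a cell the preference is diagonal, then up, then left. Returns
#' `NULL` when the best local score is 0 (no positively scoring alignment).
#'
#' @param a,b amino-acid sequences (character, [Biostrings::AAString], or a
#'   length-1 named character); allowed letters are the 20 amino acids plus X
#' @param scheme a [ScoringScheme-class] (default BLOSUM62, gap 11/1)
#' @return an [AlignmentHit-class] or `NULL`
#' @examples
#' smithWaterman("ACDE", "ACDE")  # score 24, identity 100
#' smithWaterman("AAAA", "WWWW")  # NULL
#' @export
smithWaterman <- function(a, b, scheme = scoringScheme()) {
  a <- .asProtChar(a); b <- .asProtChar(b)
  stopifnot(length(a) == 1L, length(b) == 1L, nzchar(a), nzchar(b))
  al <- .cpp_sw_align(unname(a), unname(b), scheme@matrix, .AA_ALPHABET,
                      scheme@gapOpen, scheme@gapExtend)
  if (al$score <= 0L) return(NULL)
  .hitFromRow(names(a) %||% "query", names(b) %||% "target",
              al, nchar(a), nchar(b))
}

#' All-pairs local alignment hit table
#'
#' Aligns every query against every target and returns one row per pair
#' whose local score reaches `minScore`. This is the exhaustive engine used
#' by [searchPanel()], [buildDuplicationIndex()] and core-enzyme detection;
#' write the result with `write.table` for a TSV hit table.
#'
#' @param queries,targets named character vectors or
#'   [Biostrings::AAStringSet]
#' @param scheme a [ScoringScheme-class]
#' @param minScore minimum reported local score (default 1)
#' @return data.frame with columns queryId, targetId, score,
#'   percentIdentity, queryCoverage, targetCoverage, queryStart, queryEnd,
#'   targetStart, targetEnd
#' @export
alignPairs <- function(queries, targets, scheme = scoringScheme(),
                       minScore = 1L) {
  queries <- .asProtChar(queries); targets <- .asProtChar(targets)
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  tb <- .cpp_sw_table(unname(queries), unname(targets), scheme@matrix,
                      .AA_ALPHABET, scheme@gapOpen, scheme@gapExtend,
                      as.integer(minScore))
  data.frame(
    queryId = names(queries)[tb$qi], targetId = names(targets)[tb$ti],
    score = tb$score,
    percentIdentity = 100 * tb$matches / tb$columns,
    queryCoverage = (tb$qend - tb$qstart + 1) / nchar(queries)[tb$qi],
    targetCoverage = (tb$tend - tb$tstart + 1) / nchar(targets)[tb$ti],
    queryStart = tb$qstart, queryEnd = tb$qend,
    targetStart = tb$tstart, targetEnd = tb$tend,
    stringsAsFactors = FALSE)
}

#' Search a protein against the hook panel
#'
#' Aligns one protein against every hook and returns the best qualifying
#' hit: identity at least `minIdentity` percent and coverage of the hook
#' (target) side at least `minCoverage`. Ties on score are broken by
#' lexicographic hook id. The search is exhaustive - every hook is aligned.
#'
#' @param protein amino-acid sequence (character or AAString)
#' @param panel a [HookPanel-class]
#' @param minIdentity minimum percent identity over aligned columns
#'   (default 50)
#' @param minCoverage minimum aligned fraction of the hook sequence
#'   (default 0.7)
#' @param scheme a [ScoringScheme-class]
#' @return an [AlignmentHit-class] or `NULL` when no hook qualifies
#' @export
searchPanel <- function(protein, panel, minIdentity = 50,
                        minCoverage = 0.7, scheme = scoringScheme()) {
  stopifnot(is(panel, "HookPanel"))
  if (nHooks(panel) == 0L) stop("empty hook panel")
  protein <- .asProtChar(protein)
  pname <- names(protein) %||% "query"
  tb <- alignPairs(setNames(unname(protein), pname), hookSeqs(panel),
                   scheme = scheme)
  tb <- tb[tb$percentIdentity >= minIdentity &
           tb$targetCoverage >= minCoverage, , drop = FALSE]
  if (!nrow(tb)) return(NULL)
  tb <- tb[order(-tb$score, tb$targetId), , drop = FALSE]
  r <- tb[1L, ]
  new("AlignmentHit", queryId = pname, targetId = r$targetId,
      score = as.integer(r$score), percentIdentity = r$percentIdentity,
      queryCoverage = r$queryCoverage, targetCoverage = r$targetCoverage,
      queryRange = as.integer(c(r$queryStart, r$queryEnd)),
      targetRange = as.integer(c(r$targetStart, r$targetEnd)))
}

#' Genome-wide hook duplication index
#'
#' For every hook in the panel, lists all genes of the genome hitting it at
#' the thresholds (identity on aligned columns, coverage on the hook side),
#' sorted by score descending. This is the evidence base of the duplication
#' rule: a flagged BGC needs a hook homologue inside the cluster plus at
#' least one qualifying copy outside it.
#'
#' @inheritParams searchPanel
#' @param genome a [GenomeRecord-class]
#' @return named list (one element per hook id) of data.frames with columns
#'   geneId, contig, start, end, score, percentIdentity, targetCoverage
#' @seealso [countOutsideCopies()], [resistanceScreen()]
#' @export
buildDuplicationIndex <- function(genome, panel, minIdentity = 50,
                                  minCoverage = 0.7,
                                  scheme = scoringScheme()) {
  stopifnot(is(genome, "GenomeRecord"), is(panel, "HookPanel"))
  prot <- extractProteome(genome)
  g <- genes(genome)
  pos <- data.frame(
    geneId = S4Vectors::mcols(g)$geneID,
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    stringsAsFactors = FALSE)
  empty <- data.frame(geneId = character(), contig = character(),
                      start = integer(), end = integer(), score = integer(),
                      percentIdentity = numeric(),
                      targetCoverage = numeric(), stringsAsFactors = FALSE)
  idx <- setNames(rep(list(empty), nHooks(panel)), hookIds(panel))
  if (!length(prot)) return(idx)
  tb <- alignPairs(prot, hookSeqs(panel), scheme = scheme)
  tb <- tb[tb$percentIdentity >= minIdentity &
           tb$targetCoverage >= minCoverage, , drop = FALSE]
  for (hid in names(idx)) {
    sub <- tb[tb$targetId == hid, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(-sub$score, sub$queryId), , drop = FALSE]
    df <- data.frame(geneId = sub$queryId, stringsAsFactors = FALSE)
    mi <- match(df$geneId, pos$geneId)
    df$contig <- pos$contig[mi]; df$start <- pos$start[mi]
    df$end <- pos$end[mi]
    df$score <- sub$score; df$percentIdentity <- sub$percentIdentity
    df$targetCoverage <- sub$targetCoverage
    rownames(df) <- NULL
    idx[[hid]] <- df
  }
  idx
}

#' Count hook copies outside a region
#'
#' Number of duplication-index entries for `hookId` whose gene interval does
#' not overlap the region interval; a gene on a different contig always
#' counts as outside. An unknown hook id yields 0.
#'
#' @param hookId hook identifier
#' @param regionContig contig of the region
#' @param regionRange the region interval ([IRanges::IRanges] of length 1 or
#'   a numeric `c(start, end)`, 1-based closed)
#' @param dupIndex output of [buildDuplicationIndex()] for the same genome
#' @return non-negative integer
#' @export
countOutsideCopies <- function(hookId, regionContig, regionRange, dupIndex) {
  if (is(regionRange, "IRanges"))
    regionRange <- c(IRanges::start(regionRange), IRanges::end(regionRange))
  df <- dupIndex[[hookId]]
  if (is.null(df) || !nrow(df)) return(0L)
  outside <- df$contig != regionContig |
    df$end < regionRange[1] | df$start > regionRange[2]
  sum(outside)
}
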