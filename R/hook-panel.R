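.MIN_HOOK_LENGTH <- 50L

.newPanel <- function(panelId, ids, seqs, meta) {
  new("HookPanel", panelId = panelId,
      sequences = Biostrings::AAStringSet(setNames(seqs, ids)),
      meta = S4Vectors::DataFrame(
        hookId = ids,
        sourceLocus = meta$sourceLocus, category = meta$category,
        annotation = meta$annotation))
}

#' Load a hook panel from FASTA + metadata TSV
#'
#' The FASTA holds the hook protein sequences (record ids = hook ids); the
#' TSV carries columns `hook_id`, `source_locus`, `category`, `annotation`.
#' Every FASTA record must have a metadata row and vice versa (hard error
#' listing the offending ids). Hooks sharing an identical sequence are
#' collapsed, keeping the first id, with a warning; hooks shorter than 50
#' residues are rejected - at that length the identity/coverage thresholds
#' of the screen are meaningless.
#'
#' @param fastaPath amino-acid FASTA
#' @param metadataTsv metadata TSV (see above)
#' @param panelId label for the panel (defaults to the FASTA file name)
#' @return a [HookPanel-class]
#' @examples
#' panel <- loadPanel(
#'   system.file("extdata", "hooks_synthetic.faa", package = "resMiner"),
#'   system.file("extdata", "hooks_synthetic.tsv", package = "resMiner"))
#' panel
#' @export
loadPanel <- function(fastaPath, metadataTsv,
                      panelId = basename(fastaPath)) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  md <- .readTsv(metadataTsv)
  need <- c("hook_id", "source_locus", "category", "annotation")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("panel metadata lacks column(s): ", paste(miss, collapse = ", "))
  noMeta <- setdiff(names(seqs), md$hook_id)
  noSeq <- setdiff(md$hook_id, names(seqs))
  if (length(noMeta) || length(noSeq))
    stop("panel FASTA/metadata mismatch; ",
         if (length(noMeta)) paste0("records without metadata: ",
                                    paste(noMeta, collapse = ", "), "; "),
         if (length(noSeq)) paste0("metadata without sequence: ",
                                   paste(noSeq, collapse = ", ")))
  md <- md[match(names(seqs), md$hook_id), ]
  short <- Biostrings::width(seqs) < .MIN_HOOK_LENGTH
  if (any(short))
    stop("hook(s) shorter than ", .MIN_HOOK_LENGTH, " aa: ",
         paste(names(seqs)[short], collapse = ", "))
  dup <- duplicated(as.character(seqs))
  if (any(dup)) {
    warning("collapsing hooks with identical sequences: ",
            paste(names(seqs)[dup], collapse = ", "), call. = FALSE)
    seqs <- seqs[!dup]; md <- md[!dup, ]
  }
  .newPanel(panelId, names(seqs), as.character(seqs),
            list(sourceLocus = md$source_locus, category = md$category,
                 annotation = md$annotation))
}

#' Serialize a hook panel to a single TSV
#'
#' Writes one row per hook with columns `hook_id`, `source_locus`,
#' `category`, `annotation`, `sequence`. [readPanelTsv()] restores the
#' panel exactly (round trip).
#'
#' @param panel a [HookPanel-class]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
writePanel <- function(panel, path) {
  md <- hookMeta(panel)
  .writeTsv(data.frame(
    hook_id = md$hookId, source_locus = md$sourceLocus,
    category = md$category, annotation = md$annotation,
    sequence = as.character(hookSeqs(panel)), stringsAsFactors = FALSE),
    path)
}

#' @rdname writePanel
#' @param panelId label for the restored panel
#' @export
readPanelTsv <- function(path, panelId = basename(path)) {
  df <- .readTsv(path)
  .newPanel(panelId, df$hook_id, df$sequence,
            list(sourceLocus = df$source_locus, category = df$category,
                 annotation = df$annotation))
}

#' The small built-in synthetic hook panel
#'
#' Eight synthetic housekeeping hooks (sequences are random fixed-seed
#' stand-ins, not the real proteins; annotations name the enzyme class each
#' stands for, e.g. acetolactate synthase). Suitable for examples, tests
#' and the synthetic benchmark suite.
#'
#' @return a [HookPanel-class] of 8 hooks
#' @export
builtinPanel <- function() {
  loadPanel(
    system.file("extdata", "hooks_synthetic.faa", package = "resMiner"),
    system.file("extdata", "hooks_synthetic.tsv", package = "resMiner"),
    panelId = "builtin_synthetic")
}

#' Build a hook panel by conservation screening
#'
#' Operationalizes "highly conserved protein" selection: a reference protein
#' becomes a hook iff it has a reciprocal best hit (RBH) at
#' `>= minIdentity` percent identity and `>= minCoverage` coverage of both
#' sequences in at least `ceiling(minFraction * n_comparators)` comparator
#' proteomes. All retained hooks get category `housekeeping`.
#'
#' @param referenceProteome named character vector or
#'   [Biostrings::AAStringSet] - the proteome hooks are drawn from
#' @param comparatorProteomes list (>= 1) of proteomes in the same form
#' @param minIdentity minimum RBH percent identity (default 40)
#' @param minCoverage minimum aligned fraction of both sequences
#'   (default 0.6)
#' @param minFraction fraction of comparators that must conserve the
#'   protein (default 0.8)
#' @param scheme a [ScoringScheme-class]
#' @param panelId label for the panel
#' @return a [HookPanel-class]
#' @export
buildPanel <- function(referenceProteome, comparatorProteomes,
                       minIdentity = 40, minCoverage = 0.6,
                       minFraction = 0.8, scheme = scoringScheme(),
                       panelId = "built_panel") {
  ref <- .asProtChar(referenceProteome)
  if (!length(ref)) stop("empty reference proteome")
  if (is.null(names(ref))) names(ref) <- paste0("ref", seq_along(ref))
  if (!is.list(comparatorProteomes) || !length(comparatorProteomes))
    stop("at least one comparator proteome is required")
  nComp <- length(comparatorProteomes)
  needed <- ceiling(minFraction * nComp)

  conserved <- matrix(FALSE, nrow = length(ref), ncol = nComp)
  for (ci in seq_len(nComp)) {
    comp <- .asProtChar(comparatorProteomes[[ci]])
    if (is.null(names(comp))) names(comp) <- paste0("c", seq_along(comp))
    tb <- alignPairs(ref, comp, scheme = scheme)
    tb <- tb[tb$percentIdentity >= minIdentity &
             tb$queryCoverage >= minCoverage &
             tb$targetCoverage >= minCoverage, , drop = FALSE]
    if (!nrow(tb)) next
    # best comparator per reference and best reference per comparator;
    # deterministic tie-break on partner id
    tb <- tb[order(tb$queryId, -tb$score, tb$targetId), , drop = FALSE]
    bestFwd <- tb[!duplicated(tb$queryId), c("queryId", "targetId")]
    tb2 <- tb[order(tb$targetId, -tb$score, tb$queryId), , drop = FALSE]
    bestRev <- tb2[!duplicated(tb2$targetId), c("queryId", "targetId")]
    key <- paste(bestFwd$queryId, bestFwd$targetId)
    revKey <- paste(bestRev$queryId, bestRev$targetId)
    rbh <- bestFwd$queryId[key %in% revKey]
    conserved[match(rbh, names(ref)), ci] <- TRUE
  }
  keep <- rowSums(conserved) >= needed
  ids <- names(ref)[keep]
  if (anyDuplicated(as.character(ref[keep]))) {
    dup <- duplicated(as.character(ref[keep]))
    warning("collapsing hooks with identical sequences: ",
            paste(ids[dup], collapse = ", "), call. = FALSE)
    ids <- ids[!dup]
  }
  .newPanel(panelId, ids, unname(ref[ids]),
            list(sourceLocus = ids,
                 category = rep("housekeeping", length(ids)),
                 annotation = rep("", length(ids))))
}
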