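.PKS_CLASSES <- c("HR-PKS", "NR-PKS")

#' Read a class-labelled core-enzyme reference FASTA
#'
#' Headers must carry a `class=` tag naming the core class of the reference
#' protein, e.g. `>HRPKS_ref class=HR-PKS`. An unlabelled header is a hard
#' error.
#'
#' @param fastaPath amino-acid FASTA with `class=` header tags
#' @return list with `seqs` (named [Biostrings::AAStringSet]) and `class`
#'   (named character, reference id -> core class)
#' @seealso [detectCoreGenes()], [builtinCoreReference()]
#' @export
readCoreReference <- function(fastaPath) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  m <- regmatches(headers, regexec("class=(\\S+)", headers))
  cls <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                "")
  if (anyNA(cls))
    stop("core reference header(s) without class= tag: ",
         paste(ids[is.na(cls)], collapse = ", "))
  bad <- setdiff(cls, .CORE_CLASSES)
  if (length(bad))
    stop("unknown core class label(s): ", paste(bad, collapse = ", "))
  names(seqs) <- ids
  list(seqs = seqs, class = setNames(cls, ids))
}

#' @rdname readCoreReference
#' @details `builtinCoreReference()` loads the shipped synthetic reference
#'   set (one fixed-seed stand-in protein per core class; not real enzyme
#'   sequences).
#' @export
builtinCoreReference <- function() {
  readCoreReference(system.file("extdata", "core_reference_synthetic.faa",
                                package = "resMiner", mustWork = TRUE))
}

#' Detect core biosynthetic enzyme genes
#'
#' Classifies each gene by similarity to a class-labelled core-protein
#' reference set. A hit qualifies at `>= minIdentity` percent identity with
#' `>= minCoverage` of the reference aligned; the gene takes the class of
#' its best-scoring qualifying reference. A gene with qualifying hits to
#' both a PKS reference and an NRPS reference on query segments whose
#' overlap is under 20% of either segment is called a PKS-NRPS hybrid.
#'
#' @param genome a [GenomeRecord-class]
#' @param coreRef output of [readCoreReference()] (default the shipped
#'   synthetic set)
#' @param minIdentity minimum percent identity (default 30)
#' @param minCoverage minimum aligned fraction of the reference
#'   (default 0.5)
#' @param scheme a [ScoringScheme-class]
#' @return named list: geneID -> [CoreSignature-class]
#' @export
detectCoreGenes <- function(genome, coreRef = builtinCoreReference(),
                            minIdentity = 30, minCoverage = 0.5,
                            scheme = scoringScheme()) {
  stopifnot(is(genome, "GenomeRecord"))
  prot <- extractProteome(genome)
  if (!length(prot)) return(list())
  tb <- alignPairs(prot, coreRef$seqs, scheme = scheme)
  tb <- tb[tb$percentIdentity >= minIdentity &
           tb$targetCoverage >= minCoverage, , drop = FALSE]
  if (!nrow(tb)) return(list())
  tb$refClass <- unname(coreRef$class[tb$targetId])

  out <- list()
  for (gid in unique(tb$queryId)) {
    ev <- tb[tb$queryId == gid, , drop = FALSE]
    ev <- ev[order(-ev$score, ev$targetId), , drop = FALSE]
    cls <- ev$refClass[1L]
    # hybrid test: best PKS segment vs best NRPS segment barely overlapping
    pks <- ev[ev$refClass %in% .PKS_CLASSES, , drop = FALSE]
    nrps <- ev[ev$refClass == "NRPS", , drop = FALSE]
    if (nrow(pks) && nrow(nrps)) {
      p <- pks[1L, ]; n <- nrps[1L, ]
      ov <- min(p$queryEnd, n$queryEnd) - max(p$queryStart, n$queryStart) + 1L
      lenP <- p$queryEnd - p$queryStart + 1L
      lenN <- n$queryEnd - n$queryStart + 1L
      if (ov < 0.2 * min(lenP, lenN)) cls <- "PKS-NRPS"
    }
    evidence <- data.frame(
      refId = ev$targetId, refClass = ev$refClass, score = ev$score,
      percentIdentity = ev$percentIdentity, refCoverage = ev$targetCoverage,
      queryStart = ev$queryStart, queryEnd = ev$queryEnd,
      stringsAsFactors = FALSE)
    out[[gid]] <- new("CoreSignature", coreClass = cls, evidence = evidence)
  }
  out
}

# build a BGCRegion from gene indices into a genome's sorted gene GRanges
.regionFromIdx <- function(genome, idx, regionId, cores,
                           hookHits = list(), flagged = FALSE) {
  g <- genes(genome)[idx]
  gid <- S4Vectors::mcols(g)$geneID
  new("BGCRegion",
      regionId = regionId, assemblyId = assemblyId(genome),
      contigId = as.character(GenomicRanges::seqnames(g))[1L],
      genus = genusName(genome), taxonomicClass = taxonomicClass(genome),
      range = IRanges::IRanges(min(GenomicRanges::start(g)),
                               max(GenomicRanges::end(g))),
      genes = g,
      cores = cores[intersect(names(cores), gid)],
      hookHits = hookHits, flagged = flagged)
}

#' Assemble candidate BGC regions around core genes
#'
#' Each core gene seeds a window that grows gene-by-gene in both directions
#' while at most `maxIntergenes` genes have been added on that side and the
#' genomic gap to the previous gene does not exceed `maxGapBp`. Overlapping
#' windows on the same contig are merged. Region ids are deterministic:
#' assembly, contig, ordinal along the contig.
#'
#' @param genome a [GenomeRecord-class]
#' @param coreGenes output of [detectCoreGenes()] on the same genome
#' @param maxIntergenes maximum genes added on each side of a core
#'   (default 4)
#' @param maxGapBp maximum intergenic distance in bp (default 10000)
#' @return list of [BGCRegion-class] (unflagged, hook hits not yet filled)
#' @export
assembleRegions <- function(genome, coreGenes, maxIntergenes = 4L,
                            maxGapBp = 10000L) {
  stopifnot(is(genome, "GenomeRecord"))
  if (!length(coreGenes)) return(list())
  g <- genes(genome)
  gid <- S4Vectors::mcols(g)$geneID
  bad <- setdiff(names(coreGenes), gid)
  if (length(bad))
    stop("core call for unknown gene(s): ", paste(bad, collapse = ", "))
  ctg <- as.character(GenomicRanges::seqnames(g))
  st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)

  regions <- list()
  for (cName in unique(ctg)) {
    onCtg <- which(ctg == cName)   # sorted by start already
    coreLocal <- which(gid[onCtg] %in% names(coreGenes))
    if (!length(coreLocal)) next
    windows <- lapply(coreLocal, function(ci) {
      L <- ci
      while (L > 1L && (ci - L) < maxIntergenes &&
             st[onCtg[L]] - en[onCtg[L - 1L]] - 1L <= maxGapBp)
        L <- L - 1L
      R <- ci
      while (R < length(onCtg) && (R - ci) < maxIntergenes &&
             st[onCtg[R + 1L]] - en[onCtg[R]] - 1L <= maxGapBp)
        R <- R + 1L
      c(L, R)
    })
    # merge windows overlapping in gene-index space
    windows <- windows[order(vapply(windows, `[`, 0, 1L))]
    merged <- list(windows[[1L]])
    for (w in windows[-1L]) {
      last <- merged[[length(merged)]]
      if (w[1L] <= last[2L] + 1L)
        merged[[length(merged)]] <- c(last[1L], max(last[2L], w[2L]))
      else merged <- c(merged, list(w))
    }
    for (w in merged) {
      regions <- c(regions, list(list(contig = cName, idx = onCtg[w[1L]:w[2L]])))
    }
  }
  # deterministic ids: assembly, contig order, ordinal
  out <- vector("list", length(regions))
  ord <- order(vapply(regions, function(r) match(r$contig, names(contigs(genome))), 0),
               vapply(regions, function(r) st[r$idx[1L]], 0))
  regions <- regions[ord]
  counter <- integer(0)
  for (i in seq_along(regions)) {
    cName <- regions[[i]]$contig
    counter[cName] <- (counter[cName] %||% 0L)
    counter[cName] <- if (is.na(counter[cName])) 1L else counter[cName] + 1L
    rid <- sprintf("%s_%s_r%02d", assemblyId(genome), cName, counter[cName])
    out[[i]] <- .regionFromIdx(genome, regions[[i]]$idx, rid, coreGenes)
  }
  out
}

#' Cross-genome gene occurrence index
#'
#' For each gene, the fraction of the other input genomes that contain at
#' least one homologue at the thresholds (identity on aligned columns,
#' coverage of the gene itself). Genuine cluster genes show restricted
#' occurrence across genomes while flanking housekeeping-like genes are
#' widely distributed - this index drives [delineateBoundaries()].
#'
#' @param genomes list of >= 2 [GenomeRecord-class] with globally unique
#'   gene ids
#' @param geneIds optional character vector restricting the index to these
#'   genes (default: all genes of all genomes)
#' @param minIdentity minimum percent identity (default 50)
#' @param minCoverage minimum aligned fraction of the query gene
#'   (default 0.6)
#' @param scheme a [ScoringScheme-class]
#' @return named numeric vector: geneID -> occurrence fraction in [0,1]
#' @export
buildOccurrenceIndex <- function(genomes, geneIds = NULL, minIdentity = 50,
                                 minCoverage = 0.6,
                                 scheme = scoringScheme()) {
  if (length(genomes) < 2L)
    stop("occurrence index requires >= 2 genomes; ",
         "for single-genome runs skip boundary trimming")
  prots <- lapply(genomes, extractProteome)
  allIds <- unlist(lapply(prots, names), use.names = FALSE)
  if (anyDuplicated(allIds))
    stop("gene ids must be unique across genomes")
  nOther <- length(genomes) - 1L
  out <- numeric(0)
  for (gi in seq_along(genomes)) {
    p <- prots[[gi]]
    ids <- names(p)
    if (!is.null(geneIds)) ids <- intersect(ids, geneIds)
    if (!length(ids)) next
    targetsList <- lapply(prots[-gi], function(x) unname(as.character(x)))
    for (id in ids) {
      q <- as.character(p[[id]])
      hits <- vapply(targetsList, function(tg)
        .cpp_any_hit(q, tg, scheme@matrix, .AA_ALPHABET, scheme@gapOpen,
                     scheme@gapExtend, minIdentity, minCoverage), TRUE)
      out[id] <- sum(hits) / nOther
    }
  }
  out
}

#' Trim widely distributed genes off region flanks
#'
#' From each flank inward, removes genes whose occurrence fraction is at
#' least `cutoff`, stopping at the first gene below the cutoff. Core genes
#' and hook-hit genes are never removed and also stop trimming. The region
#' interval is recomputed from the surviving genes. Idempotent.
#'
#' @param region a [BGCRegion-class]
#' @param genome the genome the region came from
#' @param occurrenceIndex output of [buildOccurrenceIndex()] covering the
#'   region's genes
#' @param cutoff occurrence fraction at or above which a flank gene is
#'   considered widely distributed (default 0.5)
#' @return the trimmed [BGCRegion-class]
#' @export
delineateBoundaries <- function(region, genome, occurrenceIndex,
                                cutoff = 0.5) {
  stopifnot(is(region, "BGCRegion"))
  gid <- geneIds(region)
  occ <- occurrenceIndex[gid]
  if (anyNA(occ)) {
    warning("occurrence index does not cover gene(s): ",
            paste(gid[is.na(occ)], collapse = ", "),
            "; treating them as occurrence 0", call. = FALSE)
    occ[is.na(occ)] <- 0
  }
  protected <- gid %in% c(names(region@cores), names(region@hookHits))
  keepFrom <- 1L
  while (keepFrom <= length(gid) && !protected[keepFrom] &&
         occ[keepFrom] >= cutoff)
    keepFrom <- keepFrom + 1L
  keepTo <- length(gid)
  while (keepTo >= keepFrom && !protected[keepTo] && occ[keepTo] >= cutoff)
    keepTo <- keepTo - 1L
  if (keepFrom == 1L && keepTo == length(gid)) return(region)
  keep <- gid[keepFrom:keepTo]
  idx <- match(keep, S4Vectors::mcols(genes(genome))$geneID)
  .regionFromIdx(genome, idx, region@regionId, region@cores,
                 region@hookHits[intersect(names(region@hookHits), keep)],
                 region@flagged)
}

#' Apply the resistance screen to a region
#'
#' Populates `hookHits` for every member gene with a qualifying hook-panel
#' hit, attaches the count of qualifying hook copies outside the region
#' (from the duplication index), and sets `flagged` to TRUE iff some hook
#' hit has at least one outside copy - the self-resistance rule: the
#' cluster encodes a diverged copy of an essential enzyme while the genome
#' keeps its intact housekeeping copy elsewhere.
#'
#' @param region a [BGCRegion-class]
#' @param genome the genome the region came from
#' @param panel a [HookPanel-class]
#' @param dupIndex output of [buildDuplicationIndex()] for this genome and
#'   panel
#' @param minIdentity,minCoverage hook-hit thresholds as in [searchPanel()]
#' @param scheme a [ScoringScheme-class]
#' @return the screened [BGCRegion-class]
#' @export
resistanceScreen <- function(region, genome, panel, dupIndex,
                             minIdentity = 50, minCoverage = 0.7,
                             scheme = scoringScheme()) {
  stopifnot(is(region, "BGCRegion"), is(panel, "HookPanel"))
  g <- genes(region)
  mc <- S4Vectors::mcols(g)
  hookHits <- list()
  for (i in seq_along(g)) {
    hit <- searchPanel(setNames(mc$protein[i], mc$geneID[i]), panel,
                       minIdentity = minIdentity, minCoverage = minCoverage,
                       scheme = scheme)
    if (is.null(hit)) next
    oc <- countOutsideCopies(hit@targetId, region@contigId, region@range,
                             dupIndex)
    hookHits[[mc$geneID[i]]] <- list(hookId = hit@targetId, hit = hit,
                                     outsideCopies = as.integer(oc))
  }
  flagged <- length(hookHits) > 0L &&
    any(vapply(hookHits, function(h) h$outsideCopies, 0L) >= 1L)
  methods::initialize(region, hookHits = hookHits, flagged = flagged)
}

#' Tabulate regions
#'
#' One row per region with the fields of the standard region table TSV.
#'
#' @param regions list of [BGCRegion-class]
#' @return data.frame with columns region_id, assembly_id, contig, start,
#'   end, n_genes, core_classes, hook_id, hook_identity, outside_copies,
#'   flagged
#' @export
regionTable <- function(regions) {
  rows <- lapply(regions, function(r) {
    hh <- r@hookHits
    best <- NULL
    if (length(hh)) {
      sc <- vapply(hh, function(h) h$hit@score, 0L)
      best <- hh[[order(-sc, names(hh))[1L]]]
    }
    data.frame(
      region_id = r@regionId, assembly_id = r@assemblyId,
      contig = r@contigId,
      start = IRanges::start(r@range), end = IRanges::end(r@range),
      n_genes = length(r@genes),
      core_classes = paste(sort(unique(vapply(r@cores, function(co) co@coreClass, ""))),
                           collapse = ","),
      hook_id = if (is.null(best)) "" else best$hookId,
      hook_identity = if (is.null(best)) NA_real_
                      else round(best$hit@percentIdentity, 1),
      outside_copies = if (is.null(best)) 0L else best$outsideCopies,
      flagged = r@flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
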