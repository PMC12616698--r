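#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

.HOOK_CATEGORIES <- c("housekeeping", "fda_drug_target", "disease_related")
.CORE_CLASSES <- c("HR-PKS", "NR-PKS", "PKS-NRPS", "NRPS", "NRPS-like",
                   "terpene_synthase", "prenyltransferase")
.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

#' Substitution matrix and gap penalties for protein local alignment
#'
#' Encapsulates the scoring model of the Smith-Waterman engine: a
#' substitution matrix (BLOSUM62 by default) restricted to the 20 amino
#' acids plus `X`, with `X` scoring 0 against every residue, and affine gap
#' penalties where a gap of length *k* costs `gapOpen + k * gapExtend`.
#'
#' @slot matrixName name of the shipped matrix ("BLOSUM62" or "BLOSUM45")
#' @slot matrix integer substitution matrix with residue dimnames
#' @slot gapOpen gap opening penalty (positive integer, default 11)
#' @slot gapExtend gap extension penalty (positive integer, default 1)
#' @seealso [scoringScheme()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrixName = "character", matrix = "matrix",
                 gapOpen = "integer", gapExtend = "integer"),
  validity = function(object) {
    if (object@gapOpen < object@gapExtend || object@gapExtend < 1L)
      return("gapOpen >= gapExtend >= 1 required")
    if (!identical(rownames(object@matrix), colnames(object@matrix)))
      return("substitution matrix must have identical row/column names")
    TRUE
  })

#' A single pairwise local-alignment hit
#'
#' @slot queryId,targetId sequence identifiers
#' @slot score optimal local alignment score (positive integer)
#' @slot percentIdentity identical columns / aligned columns x 100
#' @slot queryCoverage,targetCoverage aligned span / sequence length, in (0,1]
#' @slot queryRange,targetRange 1-based closed aligned spans (length-2 integer)
#' @exportClass AlignmentHit
setClass("AlignmentHit",
  representation(queryId = "character", targetId = "character",
                 score = "integer", percentIdentity = "numeric",
                 queryCoverage = "numeric", targetCoverage = "numeric",
                 queryRange = "integer", targetRange = "integer"),
  validity = function(object) {
    if (object@score < 1L) return("score must be positive")
    if (object@percentIdentity < 0 || object@percentIdentity > 100)
      return("percentIdentity outside [0, 100]")
    if (any(c(object@queryCoverage, object@targetCoverage) <= 0) ||
        any(c(object@queryCoverage, object@targetCoverage) > 1))
      return("coverages must lie in (0, 1]")
    if (length(object@queryRange) != 2L || length(object@targetRange) != 2L)
      return("ranges must be length-2 integer vectors")
    TRUE
  })

#' An annotated genome assembly
#'
#' One assembly with its contig sequences and protein-coding gene models.
#' Gene models are held as a [GenomicRanges::GRanges] sorted by contig and
#' start, with metadata columns `geneID`, `protein` (amino-acid sequence,
#' trailing stop removed), `product` (free-text annotation) and `exons`
#' (an [IRanges::IRangesList] of genomic exon intervals).
#'
#' @slot assemblyId assembly accession or label
#' @slot organism organism name
#' @slot genus genus label (from sidecar taxon metadata)
#' @slot taxonomicClass taxonomic class, e.g. "Eurotiomycetes"
#' @slot contigs [Biostrings::DNAStringSet] of contig sequences
#' @slot genes [GenomicRanges::GRanges] of gene models (see Details)
#' @seealso [readGenome()], [readGenBank()], [extractProteome()]
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(assemblyId = "character", organism = "character",
                 genus = "character", taxonomicClass = "character",
                 contigs = "DNAStringSet", genes = "GRanges"),
  validity = function(object) {
    g <- object@genes
    mc <- S4Vectors::mcols(g)
    need <- c("geneID", "protein", "product", "exons")
    if (!all(need %in% colnames(mc)))
      return(paste("genes must carry mcols:", paste(need, collapse = ", ")))
    if (anyDuplicated(mc$geneID)) return("gene IDs must be unique")
    if (length(g)) {
      if (!all(as.character(GenomicRanges::seqnames(g)) %in%
               names(object@contigs)))
        return("gene references a contig absent from the assembly")
      cl <- setNames(Biostrings::width(object@contigs), names(object@contigs))
      if (any(GenomicRanges::end(g) >
              cl[as.character(GenomicRanges::seqnames(g))]))
        return("gene interval extends beyond its contig")
      if (any(!nzchar(mc$protein))) return("empty protein sequence")
    }
    TRUE
  })

#' Panel of housekeeping / drug-target hook proteins
#'
#' The bait set for resistance-gene-guided mining. Each hook carries a
#' category (`housekeeping`, `fda_drug_target` or `disease_related`), a
#' source locus tag and a free-text annotation. Hook identifiers are unique
#' and no two hooks share an identical sequence.
#'
#' @slot panelId panel label
#' @slot sequences [Biostrings::AAStringSet] named by hook id
#' @slot meta [S4Vectors::DataFrame] with columns hookId, sourceLocus,
#'   category, annotation (parallel to `sequences`)
#' @seealso [loadPanel()], [buildPanel()], [writePanel()]
#' @exportClass HookPanel
setClass("HookPanel",
  representation(panelId = "character", sequences = "AAStringSet",
                 meta = "DataFrame"),
  validity = function(object) {
    ids <- names(object@sequences)
    if (anyDuplicated(ids)) return("hook ids must be unique")
    if (!identical(ids, object@meta$hookId))
      return("metadata rows must parallel sequences")
    if (anyDuplicated(as.character(object@sequences)))
      return("duplicate hook sequences are not allowed")
    if (!all(object@meta$category %in% .HOOK_CATEGORIES))
      return(paste("category must be one of:",
                   paste(.HOOK_CATEGORIES, collapse = ", ")))
    if (length(object@sequences) &&
        any(Biostrings::width(object@sequences) < 1L))
      return("empty hook sequence")
    TRUE
  })

#' Core-enzyme call for one gene
#'
#' @slot coreClass one of HR-PKS, NR-PKS, PKS-NRPS, NRPS, NRPS-like,
#'   terpene_synthase, prenyltransferase
#' @slot evidence data.frame of qualifying reference hits (refId, refClass,
#'   score, percentIdentity, refCoverage, queryStart, queryEnd)
#' @exportClass CoreSignature
setClass("CoreSignature",
  representation(coreClass = "character", evidence = "data.frame"),
  validity = function(object) {
    if (!object@coreClass %in% .CORE_CLASSES)
      return(paste("unknown core class:", object@coreClass))
    if (nrow(object@evidence) < 1L) return("core call requires evidence")
    TRUE
  })

#' A candidate biosynthetic gene cluster region
#'
#' A contiguous run of genes around one or more core biosynthetic enzymes,
#' optionally annotated with hook hits, outside-duplicate counts and the
#' resistance flag. `genes` is a [GenomicRanges::GRanges] with the same
#' metadata columns as in [GenomeRecord-class], restricted to the member
#' genes, so a region is self-contained for family comparison and export.
#'
#' @slot regionId deterministic region identifier
#' @slot assemblyId,contigId provenance
#' @slot genus,taxonomicClass inherited from the genome
#' @slot range [IRanges::IRanges] of length 1 spanning all member genes
#' @slot genes member gene models (sorted by start)
#' @slot cores named list: geneID -> [CoreSignature-class]
#' @slot hookHits named list: geneID -> list(hookId, hit = AlignmentHit,
#'   outsideCopies)
#' @slot flagged TRUE iff some hook hit has at least one copy outside the
#'   region (the resistance rule)
#' @exportClass BGCRegion
setClass("BGCRegion",
  representation(regionId = "character", assemblyId = "character",
                 contigId = "character", genus = "character",
                 taxonomicClass = "character", range = "IRanges",
                 genes = "GRanges", cores = "list", hookHits = "list",
                 flagged = "logical"),
  validity = function(object) {
    if (length(object@range) != 1L) return("range must have length 1")
    if (length(object@cores) < 1L) return("a region requires >= 1 core gene")
    st <- GenomicRanges::start(object@genes)
    if (is.unsorted(st)) return("member genes must be sorted by start")
    if (length(object@genes) &&
        (min(st) < IRanges::start(object@range) ||
         max(GenomicRanges::end(object@genes)) > IRanges::end(object@range)))
      return("range must cover all member genes")
    gid <- S4Vectors::mcols(object@genes)$geneID
    if (!all(names(object@cores) %in% gid))
      return("core call for a non-member gene")
    if (!all(names(object@hookHits) %in% gid))
      return("hook hit for a non-member gene")
    if (isTRUE(object@flagged)) {
      oc <- vapply(object@hookHits, function(h) h$outsideCopies, 0L)
      if (!length(oc) || max(oc) < 1L)
        return("flagged region lacks a hook hit with an outside copy")
    }
    TRUE
  })

#' A refined gene-cluster family
#'
#' @slot familyId deterministic family identifier
#' @slot members list of [BGCRegion-class]
#' @slot coreSignature sorted multiset of member core classes
#' @slot hookSignature shared hook id ("" before refinement when mixed)
#' @slot genera distinct member genera
#' @slot classCounts named integer: taxonomic class -> member count
#' @exportClass Family
setClass("Family",
  representation(familyId = "character", members = "list",
                 coreSignature = "character", hookSignature = "character",
                 genera = "character", classCounts = "integer"),
  validity = function(object) {
    if (length(object@members) < 1L) return("family needs >= 1 member")
    if (!all(vapply(object@members, is, TRUE, "BGCRegion")))
      return("members must be BGCRegion objects")
    if (sum(object@classCounts) != length(object@members))
      return("classCounts must sum to the member count")
    TRUE
  })
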