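#' @name accessors
#' @title Accessors for resMiner classes
#' @description Slot accessors for [GenomeRecord-class], [HookPanel-class],
#'   [BGCRegion-class] and [Family-class] objects. Use these rather than
#'   `@` access.
#' @param x an object of the documented classes
#' @return the corresponding slot value
NULL

#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setGeneric("organismName", function(x) standardGeneric("organismName"))
#' @rdname accessors
#' @export
setGeneric("genusName", function(x) standardGeneric("genusName"))
#' @rdname accessors
#' @export
setGeneric("taxonomicClass", function(x) standardGeneric("taxonomicClass"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("hookIds", function(x) standardGeneric("hookIds"))
#' @rdname accessors
#' @export
setGeneric("hookSeqs", function(x) standardGeneric("hookSeqs"))
#' @rdname accessors
#' @export
setGeneric("hookMeta", function(x) standardGeneric("hookMeta"))
#' @rdname accessors
#' @export
setGeneric("nHooks", function(x) standardGeneric("nHooks"))
#' @rdname accessors
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))
#' @rdname accessors
#' @export
setGeneric("regionRange", function(x) standardGeneric("regionRange"))
#' @rdname accessors
#' @export
setGeneric("coreCalls", function(x) standardGeneric("coreCalls"))
#' @rdname accessors
#' @export
setGeneric("hookHits", function(x) standardGeneric("hookHits"))
#' @rdname accessors
#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("coreSignature", function(x) standardGeneric("coreSignature"))
#' @rdname accessors
#' @export
setGeneric("hookSignature", function(x) standardGeneric("hookSignature"))

#' Extract the proteome of a genome
#'
#' Returns one amino-acid sequence per gene model, named by gene id, in
#' deterministic order (contig, then start coordinate).
#'
#' @param genome a [GenomeRecord-class]
#' @return a named [Biostrings::AAStringSet]
#' @examples
#' gn <- exampleGenome()
#' head(names(extractProteome(gn)))
#' @export
setGeneric("extractProteome", function(genome) standardGeneric("extractProteome"))

# -------- methods --------

#' @rdname accessors
setMethod("assemblyId", "GenomeRecord", function(x) x@assemblyId)
#' @rdname accessors
setMethod("assemblyId", "BGCRegion", function(x) x@assemblyId)
#' @rdname accessors
setMethod("organismName", "GenomeRecord", function(x) x@organism)
#' @rdname accessors
setMethod("genusName", "GenomeRecord", function(x) x@genus)
#' @rdname accessors
setMethod("genusName", "BGCRegion", function(x) x@genus)
#' @rdname accessors
setMethod("taxonomicClass", "GenomeRecord", function(x) x@taxonomicClass)
#' @rdname accessors
setMethod("taxonomicClass", "BGCRegion", function(x) x@taxonomicClass)
#' @rdname accessors
setMethod("contigs", "GenomeRecord", function(x) x@contigs)
#' @rdname accessors
setMethod("genes", "GenomeRecord", function(x) x@genes)
#' @rdname accessors
setMethod("genes", "BGCRegion", function(x) x@genes)
#' @rdname accessors
setMethod("geneIds", "GenomeRecord",
          function(x) S4Vectors::mcols(x@genes)$geneID)
#' @rdname accessors
setMethod("geneIds", "BGCRegion",
          function(x) S4Vectors::mcols(x@genes)$geneID)
#' @rdname accessors
setMethod("nGenes", "GenomeRecord", function(x) length(x@genes))
#' @rdname accessors
setMethod("nGenes", "BGCRegion", function(x) length(x@genes))
#' @rdname accessors
setMethod("hookIds", "HookPanel", function(x) names(x@sequences))
#' @rdname accessors
setMethod("hookSeqs", "HookPanel", function(x) x@sequences)
#' @rdname accessors
setMethod("hookMeta", "HookPanel", function(x) x@meta)
#' @rdname accessors
setMethod("nHooks", "HookPanel", function(x) length(x@sequences))
#' @rdname accessors
setMethod("regionId", "BGCRegion", function(x) x@regionId)
#' @rdname accessors
setMethod("regionRange", "BGCRegion", function(x) x@range)
#' @rdname accessors
setMethod("coreCalls", "BGCRegion", function(x) x@cores)
#' @rdname accessors
setMethod("hookHits", "BGCRegion", function(x) x@hookHits)
#' @rdname accessors
setMethod("isFlagged", "BGCRegion", function(x) x@flagged)
#' @rdname accessors
setMethod("familyId", "Family", function(x) x@familyId)
#' @rdname accessors
setMethod("members", "Family", function(x) x@members)
#' @rdname accessors
setMethod("coreSignature", "Family", function(x) x@coreSignature)
#' @rdname accessors
setMethod("hookSignature", "Family", function(x) x@hookSignature)
#' @rdname accessors
setMethod("genusName", "Family", function(x) x@genera)
#' @rdname accessors
setMethod("taxonomicClass", "Family", function(x) x@classCounts)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@assemblyId, "\n",
      " organism:", object@organism,
      sprintf("(%s; %s)", object@genus, object@taxonomicClass), "\n",
      " contigs: ", length(object@contigs),
      sprintf("(%.1f kb)", sum(Biostrings::width(object@contigs)) / 1e3), "\n",
      " genes:  ", length(object@genes), "\n")
})

setMethod("show", "HookPanel", function(object) {
  cat("HookPanel:", object@panelId, "-", length(object@sequences),
      "hooks\n")
  tb <- table(object@meta$category)
  for (nm in names(tb)) cat("  ", nm, ":", tb[[nm]], "\n")
})

setMethod("show", "AlignmentHit", function(object) {
  cat(sprintf(
    "AlignmentHit %s ~ %s  score=%d  id=%.1f%%  cov(q)=%.2f cov(t)=%.2f\n",
    object@queryId, object@targetId, object@score, object@percentIdentity,
    object@queryCoverage, object@targetCoverage))
})

setMethod("show", "BGCRegion", function(object) {
  cores <- vapply(object@cores, function(co) co@coreClass, "")
  hooks <- vapply(object@hookHits, function(h) h$hookId, "")
  cat("BGCRegion", object@regionId,
      sprintf("[%s:%d-%d]", object@contigId, IRanges::start(object@range),
              IRanges::end(object@range)), "\n",
      " genes:", length(object@genes),
      " cores:", paste(unique(cores), collapse = ","),
      " hooks:", if (length(hooks)) paste(unique(hooks), collapse = ",")
                 else "-",
      " flagged:", object@flagged, "\n")
})

setMethod("show", "Family", function(object) {
  cat("Family", object@familyId, "-", length(object@members), "BGCs,",
      length(object@genera), "genera\n",
      " cores:", paste(object@coreSignature, collapse = "+"),
      " hook:", object@hookSignature, "\n")
})
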