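#' Assemble and validate a pipeline run configuration
#'
#' Collects inputs and thresholds for [runMine()]. Every referenced path is
#' checked at validation time; thresholds must lie in their documented
#' ranges.
#'
#' @param genomeTable data.frame with columns `fasta`, `gff` (paths) - one
#'   row per genome; alternatively a list of [GenomeRecord-class] objects
#' @param taxonTsv path to the taxon metadata TSV (required with file
#'   input; see [readTaxonTable()])
#' @param panel a [HookPanel-class], or `NULL` for [builtinPanel()]
#' @param coreRef output of [readCoreReference()], or `NULL` for the
#'   shipped set
#' @param outDir output directory
#' @param thresholds named list overriding any of: `hookIdentity` (50),
#'   `hookCoverage` (0.7), `coreIdentity` (30), `coreCoverage` (0.5),
#'   `occIdentity` (50), `occCoverage` (0.6), `occCutoff` (0.5),
#'   `maxIntergenes` (4), `maxGapBp` (10000), `familyCutoff` (0.3),
#'   `familyWeights` (c(0.3, 0.2, 0.5)), `matchIdentity` (40),
#'   `matchCoverage` (0.6)
#' @param seed integer seed echoed into the report (the mining pipeline
#'   itself is deterministic; the seed is a passthrough for simulation
#'   workflows)
#' @param writeGenBank write one GenBank file per flagged region
#'   (default TRUE)
#' @return a validated `RunConfig` list
#' @export
runConfig <- function(genomeTable, taxonTsv = NULL, panel = NULL,
                      coreRef = NULL, outDir, thresholds = list(),
                      seed = 1L, writeGenBank = TRUE) {
  defaults <- list(hookIdentity = 50, hookCoverage = 0.7,
                   coreIdentity = 30, coreCoverage = 0.5,
                   occIdentity = 50, occCoverage = 0.6, occCutoff = 0.5,
                   maxIntergenes = 4L, maxGapBp = 10000L,
                   familyCutoff = 0.3, familyWeights = c(0.3, 0.2, 0.5),
                   matchIdentity = 40, matchCoverage = 0.6)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  th <- utils::modifyList(defaults, thresholds)
  for (nm in c("hookIdentity", "coreIdentity", "occIdentity",
               "matchIdentity"))
    if (th[[nm]] < 0 || th[[nm]] > 100)
      stop(nm, " must lie in [0, 100]")
  for (nm in c("hookCoverage", "coreCoverage", "occCoverage", "occCutoff",
               "familyCutoff", "matchCoverage"))
    if (th[[nm]] < 0 || th[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")

  preloaded <- is.list(genomeTable) && !is.data.frame(genomeTable)
  if (preloaded) {
    if (!length(genomeTable)) stop("empty genome list")
    stopifnot(all(vapply(genomeTable, is, TRUE, "GenomeRecord")))
  } else {
    if (!is.data.frame(genomeTable) || !nrow(genomeTable))
      stop("empty genome list")
    stopifnot(all(c("fasta", "gff") %in% colnames(genomeTable)))
    missing <- c(genomeTable$fasta[!file.exists(genomeTable$fasta)],
                 genomeTable$gff[!file.exists(genomeTable$gff)])
    if (is.null(taxonTsv)) stop("taxonTsv is required with file input")
    if (!file.exists(taxonTsv)) missing <- c(missing, taxonTsv)
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(genomeTable = genomeTable, taxonTsv = taxonTsv,
                 panel = panel %||% builtinPanel(),
                 coreRef = coreRef %||% builtinCoreReference(),
                 outDir = outDir, thresholds = th,
                 seed = as.integer(seed), writeGenBank = writeGenBank),
            class = "RunConfig")
}

.loadConfigGenomes <- function(config) {
  if (is.list(config$genomeTable) && !is.data.frame(config$genomeTable))
    return(config$genomeTable)
  taxa <- readTaxonTable(config$taxonTsv)
  lapply(seq_len(nrow(config$genomeTable)), function(i) {
    fa <- config$genomeTable$fasta[i]
    gff <- config$genomeTable$gff[i]
    asm <- sub("\\.(fna|fa|fasta)$", "", basename(fa))
    row <- taxa[match(asm, taxa$assembly_id), ]
    if (nrow(row) != 1L || anyNA(row$assembly_id))
      stop("no taxon metadata for assembly '", asm, "'")
    readGenome(fa, gff, row)
  })
}

#' Run the full resistance-gene-guided mining pipeline
#'
#' Executes, per genome: core-enzyme detection, region assembly around
#' cores, the duplication index, and the resistance screen; then, with two
#' or more genomes, occurrence-based boundary delineation of the flagged
#' regions; then single-linkage family clustering of all flagged regions,
#' refinement to shared (core signature, hook), the single-genus filter,
#' and the taxonomy summary. All tables, per-region GenBank files, a
#' `report.json` and a `MANIFEST` are written under `config$outDir`. On a
#' stage error, partial outputs are retained and the MANIFEST marks the run
#' incomplete before the error propagates.
#'
#' @param config a `RunConfig` from [runConfig()]
#' @return a `RunReport` list (regions, flagged regions, families before
#'   and after refinement/filtering, taxonomy summary, notices, provenance)
#' @seealso [renderReport()], [evaluateRecovery()]
#' @export
runMine <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  scheme <- scoringScheme()
  written <- character(0)
  note <- character(0)
  emit <- function(rel) written <<- c(written, rel)
  writeManifest <- function(status) {
    mf <- file.path(config$outDir, "MANIFEST")
    writeLines(c("# resMiner run MANIFEST",
                 paste0("status: ", status),
                 sort(unique(c(written, "MANIFEST")))), mf)
  }

  result <- tryCatch({
    genomes <- .loadConfigGenomes(config)
    asmIds <- vapply(genomes, assemblyId, "")
    if (anyDuplicated(asmIds)) stop("duplicate assembly ids")

    regionsByGenome <- list()
    flagged <- list()
    for (gn in genomes) {
      cores <- detectCoreGenes(gn, config$coreRef,
                               minIdentity = th$coreIdentity,
                               minCoverage = th$coreCoverage,
                               scheme = scheme)
      regs <- assembleRegions(gn, cores, maxIntergenes = th$maxIntergenes,
                              maxGapBp = th$maxGapBp)
      dup <- buildDuplicationIndex(gn, config$panel,
                                   minIdentity = th$hookIdentity,
                                   minCoverage = th$hookCoverage,
                                   scheme = scheme)
      regs <- lapply(regs, resistanceScreen, genome = gn,
                     panel = config$panel, dupIndex = dup,
                     minIdentity = th$hookIdentity,
                     minCoverage = th$hookCoverage, scheme = scheme)
      regionsByGenome[[assemblyId(gn)]] <-
        list(genome = gn, regions = regs)
      rt <- regionTable(regs) %||% data.frame()
      rel <- sprintf("regions_%s.tsv", assemblyId(gn))
      .writeTsv(rt, file.path(config$outDir, rel)); emit(rel)
    }

    if (length(genomes) >= 2L) {
      flaggedIds <- unlist(lapply(regionsByGenome, function(x)
        lapply(Filter(isFlagged, x$regions), geneIds)))
      occ <- buildOccurrenceIndex(genomes, geneIds = flaggedIds,
                                  minIdentity = th$occIdentity,
                                  minCoverage = th$occCoverage,
                                  scheme = scheme)
      for (asm in names(regionsByGenome)) {
        x <- regionsByGenome[[asm]]
        x$regions <- lapply(x$regions, function(r) {
          if (!isFlagged(r)) return(r)
          delineateBoundaries(r, x$genome, occ, cutoff = th$occCutoff)
        })
        regionsByGenome[[asm]] <- x
      }
    } else {
      note <- c(note, "single-genome run: boundary trimming skipped")
    }
    flagged <- unlist(lapply(regionsByGenome, function(x)
      Filter(isFlagged, x$regions)), use.names = FALSE) %||% list()

    fr <- regionTable(flagged) %||% data.frame()
    .writeTsv(fr, file.path(config$outDir, "flagged_regions.tsv"))
    emit("flagged_regions.tsv")

    if (config$writeGenBank && length(flagged)) {
      dir.create(file.path(config$outDir, "gbk"), showWarnings = FALSE)
      for (r in flagged) {
        gn <- regionsByGenome[[r@assemblyId]]$genome
        rel <- file.path("gbk", paste0(r@regionId, ".gbk"))
        writeBgcGenBank(gn, r, file.path(config$outDir, rel)); emit(rel)
      }
    }

    fams <- clusterFamilies(flagged, cutoff = th$familyCutoff,
                            weights = th$familyWeights,
                            minIdentity = th$matchIdentity,
                            minCoverage = th$matchCoverage, scheme = scheme)
    refined <- refineFamilies(fams)
    final <- dropSingleGenus(refined)
    tax <- taxonomySummary(final)

    .writeTsv(familyTable(final), file.path(config$outDir, "families.tsv"))
    emit("families.tsv")
    .writeTsv(tax$byFamily, file.path(config$outDir, "taxonomy.tsv"))
    emit("taxonomy.tsv")

    hookAnn <- setNames(hookMeta(config$panel)$annotation,
                        hookIds(config$panel))
    report <- structure(list(
      schemaVersion = "1.0",
      tool = list(name = "resMiner",
                  version = as.character(utils::packageVersion("resMiner"))),
      provenance = list(assemblies = unname(asmIds),
                        panelId = config$panel@panelId,
                        nHooks = nHooks(config$panel),
                        thresholds = th, seed = config$seed),
      genomes = data.frame(assembly_id = unname(asmIds),
                           n_genes = vapply(genomes, nGenes, 0L),
                           genus = vapply(genomes, genusName, ""),
                           class = vapply(genomes, taxonomicClass, ""),
                           stringsAsFactors = FALSE),
      regionsByGenome = lapply(regionsByGenome, function(x)
        regionTable(x$regions) %||% data.frame()),
      flaggedRegions = flagged,
      flaggedTable = fr,
      families = fams, familiesRefined = refined, familiesFinal = final,
      familyTable = familyTable(final),
      hookAnnotations = as.list(hookAnn),
      taxonomy = tax,
      notices = note), class = "RunReport")

    renderReport(report, "json", file.path(config$outDir, "report.json"))
    emit("report.json")
    writeManifest("complete")
    report
  }, error = function(e) {
    writeManifest("incomplete")
    stop(e)
  })
  invisible(result)
}

# JSON-serializable view of a report (S4 regions/families flattened to
# tables; deterministic for identical runs - no timestamps)
.reportPayload <- function(report) {
  list(schemaVersion = report$schemaVersion,
       tool = report$tool,
       provenance = report$provenance,
       genomes = report$genomes,
       regionsByGenome = report$regionsByGenome,
       flaggedRegions = report$flaggedTable,
       families = report$familyTable,
       familiesRefined = familyTable(report$familiesRefined) %||%
         data.frame(),
       taxonomy = list(byFamily = report$taxonomy$byFamily,
                       classTotals = as.list(report$taxonomy$classTotals)),
       hookAnnotations = report$hookAnnotations,
       notices = report$notices)
}

#' Render a run report to JSON or HTML
#'
#' The JSON rendering is schema-versioned, contains no timestamps, and is
#' byte-identical across reruns with identical inputs; parse it back with
#' [readReportJson()]. The HTML rendering shows one card per family with a
#' gene-arrow diagram of each member region and the hook annotation text.
#'
#' @param report a `RunReport` from [runMine()]
#' @param format `"json"` or `"html"`
#' @param path output file
#' @return `path`, invisibly
#' @export
renderReport <- function(report, format = c("json", "html"), path) {
  stopifnot(inherits(report, "RunReport"))
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(.reportPayload(report), auto_unbox = TRUE,
                             digits = 10, pretty = TRUE, na = "null")
    writeLines(json, path)
  } else {
    writeLines(.renderHtml(report), path)
  }
  invisible(path)
}

#' @rdname renderReport
#' @export
readReportJson <- function(path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)

.geneArrowSvg <- function(region) {
  g <- genes(region)
  if (!length(g)) return("")
  rs <- IRanges::start(region@range)
  span <- max(IRanges::width(region@range), 1L)
  scale <- 700 / span
  shapes <- vapply(seq_along(g), function(i) {
    x1 <- (GenomicRanges::start(g)[i] - rs) * scale + 20
    x2 <- (GenomicRanges::end(g)[i] - rs) * scale + 20
    gid <- S4Vectors::mcols(g)$geneID[i]
    fill <- if (gid %in% names(region@cores)) "#c2503c"
            else if (gid %in% names(region@hookHits)) "#3c6fc2"
            else "#bbbbbb"
    fwd <- as.character(GenomicRanges::strand(g))[i] != "-"
    pts <- if (fwd)
      sprintf("%.1f,12 %.1f,12 %.1f,20 %.1f,28 %.1f,28", x1, x2 - 6, x2,
              x2 - 6, x1)
    else
      sprintf("%.1f,20 %.1f,12 %.1f,12 %.1f,28 %.1f,28", x1, x1 + 6, x2,
              x2, x1 + 6)
    sprintf('<polygon points="%s" fill="%s"><title>%s</title></polygon>',
            pts, fill, gid)
  }, "")
  sprintf('<svg width="740" height="40">%s</svg>',
          paste(shapes, collapse = ""))
}

.renderHtml <- function(report) {
  fams <- report$familiesFinal
  cards <- if (!length(fams)) {
    "<p><em>No gene-cluster families passed the screen and filters.</em></p>"
  } else {
    vapply(fams, function(f) {
      ann <- report$hookAnnotations[[f@hookSignature]] %||% ""
      memberRows <- vapply(f@members, function(r) sprintf(
        "<div class='member'><b>%s</b> (%s, %s) %s</div>",
        r@regionId, r@genus, r@taxonomicClass, .geneArrowSvg(r)), "")
      sprintf(paste0(
        "<div class='card'><h2>Family %s</h2>",
        "<p>%d BGCs, genera: %s<br/>cores: %s; hook: %s (%s)</p>%s</div>"),
        f@familyId, length(f@members), paste(f@genera, collapse = ", "),
        paste(f@coreSignature, collapse = " + "), f@hookSignature, ann,
        paste(memberRows, collapse = "\n"))
    }, "")
  }
  c("<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>resMiner report</title>",
    "<style>body{font-family:sans-serif;max-width:820px;margin:auto}",
    ".card{border:1px solid #ccc;border-radius:6px;padding:1em;margin:1em 0}",
    ".member{margin:.4em 0}</style></head><body>",
    "<h1>resMiner &mdash; resistance-gene-guided mining report</h1>",
    sprintf("<p>%d genome(s); %d flagged region(s); %d famil(ies) after refinement and genus filtering.</p>",
            nrow(report$genomes), length(report$flaggedRegions),
            length(report$familiesFinal)),
    cards,
    "</body></html>")
}
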