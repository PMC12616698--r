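# --- taxon metadata -------------------------------------------------------

# accepts a named list / vector / one-row data.frame with fields
# assembly_id, organism, genus, class
.taxonRow <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- as.list(x)
  need <- c("assembly_id", "organism", "genus", "class")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("taxon metadata lacks field(s): ", paste(miss, collapse = ", "))
  lapply(x[need], as.character)
}

#' Read the taxon metadata sidecar TSV
#'
#' Columns: `assembly_id`, `organism`, `genus`, `class`. Genus and class
#' come from this sidecar rather than being parsed out of organism strings.
#'
#' @param path TSV path
#' @return data.frame with one row per assembly
#' @export
readTaxonTable <- function(path) {
  df <- .readTsv(path)
  need <- c("assembly_id", "organism", "genus", "class")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("taxon table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

# --- splicing + translation ----------------------------------------------

# contigSeq: DNAString; exons: IRanges in genomic order; phase trims the
# 5'-most bases of the transcript
.spliceTranslate <- function(contigSeq, exons, strand, phase = 0L) {
  exons <- IRanges::reduce(exons)  # sorted, disjoint
  parts <- Biostrings::extractAt(contigSeq, exons)
  spliced <- unlist(parts)
  if (strand == "-") spliced <- Biostrings::reverseComplement(spliced)
  if (phase > 0L) spliced <- Biostrings::subseq(spliced, phase + 1L)
  if (length(spliced) %% 3L != 0L) return(NULL)
  aa <- as.character(Biostrings::translate(spliced, no.init.codon = TRUE,
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

.emptyGeneGR <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    geneID = character(), protein = character(), product = character(),
    exons = IRanges::IRangesList())
  gr
}

# assemble the sorted gene-model GRanges for a GenomeRecord
.makeGeneGR <- function(contigNames, contigLens, tab) {
  if (!length(tab$geneID)) return(.emptyGeneGR())
  gr <- GenomicRanges::GRanges(
    seqnames = factor(tab$contig, levels = contigNames),
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    seqlengths = setNames(contigLens, contigNames))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    geneID = tab$geneID, protein = tab$protein, product = tab$product,
    exons = tab$exons)
  ord <- order(match(tab$contig, contigNames), tab$start)
  gr[ord]
}

.newGenome <- function(taxon, contigs, tab) {
  new("GenomeRecord",
      assemblyId = taxon$assembly_id, organism = taxon$organism,
      genus = taxon$genus, taxonomicClass = taxon$class,
      contigs = contigs,
      genes = .makeGeneGR(names(contigs), Biostrings::width(contigs), tab))
}

# --- FASTA + GFF3 reader --------------------------------------------------

#' Read an annotated genome from FASTA + GFF3
#'
#' Builds a [GenomeRecord-class] from a nucleotide FASTA and a GFF3 with
#' gene/mRNA/CDS features (bare gene+CDS annotations are also accepted).
#' One gene model is produced per mRNA with CDS: the CDS segments are
#' spliced in genomic order, reverse-complemented for minus-strand genes,
#' phase-trimmed, and translated with the standard codon table; one trailing
#' stop is removed. Ambiguous codons translate to `X`. Transcripts beyond
#' the first per gene are ignored (fungal annotations are one-isoform).
#'
#' A feature referencing a contig absent from the FASTA is a hard error; a
#' CDS whose spliced length is not divisible by 3 causes the gene to be
#' skipped with a warning.
#'
#' @param fastaPath nucleotide FASTA of contigs
#' @param gffPath GFF3 annotation (1-based closed coordinates, phase-aware)
#' @param taxonMetadata named list / one-row data.frame with `assembly_id`,
#'   `organism`, `genus`, `class` (see [readTaxonTable()])
#' @return a [GenomeRecord-class]
#' @seealso [readGenBank()], [extractProteome()]
#' @export
readGenome <- function(fastaPath, gffPath, taxonMetadata) {
  taxon <- .taxonRow(taxonMetadata)
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gffPath, format = "gff3")

  bad <- !(as.character(GenomicRanges::seqnames(gff)) %in% names(contigs))
  if (any(bad)) {
    f <- gff[bad][1L]
    stop(sprintf("feature '%s' (%s) references unknown contig '%s'",
                 S4Vectors::mcols(f)$ID %||% "<no ID>",
                 S4Vectors::mcols(f)$type,
                 as.character(GenomicRanges::seqnames(f))))
  }

  # flatten features to plain vectors once; per-feature GRanges subsetting
  # is far too slow for genome-scale annotations
  mc <- S4Vectors::mcols(gff)
  typ <- as.character(mc$type)
  fid <- as.character(mc$ID)
  fparent <- vapply(as.list(mc$Parent),
                    function(p) if (length(p)) p[[1L]] else NA_character_,
                    "")
  fprod <- if ("product" %in% colnames(mc)) as.character(mc$product)
           else rep(NA_character_, length(gff))
  fphase <- if ("phase" %in% colnames(mc)) as.integer(mc$phase)
            else rep(NA_integer_, length(gff))
  fseq <- as.character(GenomicRanges::seqnames(gff))
  fstart <- GenomicRanges::start(gff)
  fend <- GenomicRanges::end(gff)
  fstrand <- as.character(GenomicRanges::strand(gff))

  geneIdx <- which(typ == "gene")
  mrnaIdx <- which(typ %in% c("mRNA", "transcript"))
  cdsIdx <- which(typ == "CDS")
  cdsByParent <- split(cdsIdx, fparent[cdsIdx])
  mrnaByParent <- split(mrnaIdx, fparent[mrnaIdx])

  tab <- list(geneID = character(), contig = character(), start = integer(),
              end = integer(), strand = character(), protein = character(),
              product = character(), exons = IRanges::IRangesList())
  exonAcc <- list()
  for (i in geneIdx) {
    gid <- fid[i]
    tx <- mrnaByParent[[gid]]
    if (length(tx)) {
      cds <- cdsByParent[[fid[tx[1L]]]]   # first transcript only
      prod <- fprod[tx[1L]]
    } else {
      cds <- cdsByParent[[gid]]           # bare gene + CDS
      prod <- NA_character_
    }
    if (is.na(prod)) prod <- if (!is.na(fprod[i])) fprod[i] else ""
    if (!length(cds)) next
    cds <- cds[order(fstart[cds])]
    strand <- fstrand[cds[1L]]
    phases <- fphase[cds]
    phases[is.na(phases)] <- 0L
    phase <- if (strand == "-") phases[length(cds)] else phases[1L]
    exons <- IRanges::IRanges(fstart[cds], fend[cds])
    ctg <- fseq[cds[1L]]
    aa <- .spliceTranslate(contigs[[ctg]], exons, strand, as.integer(phase))
    if (is.null(aa)) {
      warning(sprintf("gene '%s': spliced CDS length not divisible by 3; skipped",
                      gid), call. = FALSE)
      next
    }
    tab$geneID <- c(tab$geneID, gid)
    tab$contig <- c(tab$contig, ctg)
    tab$start <- c(tab$start, min(fstart[cds]))
    tab$end <- c(tab$end, max(fend[cds]))
    tab$strand <- c(tab$strand, strand)
    tab$protein <- c(tab$protein, aa)
    tab$product <- c(tab$product, prod)
    exonAcc[[length(exonAcc) + 1L]] <- exons
  }
  tab$exons <- methods::as(exonAcc, "IRangesList")
  .newGenome(taxon, contigs, tab)
}

#' @rdname extractProteome
setMethod("extractProteome", "GenomeRecord", function(genome) {
  g <- genes(genome)   # already sorted by contig, then start
  Biostrings::AAStringSet(setNames(S4Vectors::mcols(g)$protein,
                                   S4Vectors::mcols(g)$geneID))
})

#' A small bundled example genome
#'
#' Deterministically generates a single synthetic genome with one planted
#' resistant cluster, for examples and quick interactive exploration.
#'
#' @param seed integer seed (default 1)
#' @return a [GenomeRecord-class]
#' @export
exampleGenome <- function(seed = 1L) {
  cfg <- simConfig(
    nGenomes = 1L,
    taxa = data.frame(genus = "Aspergillus", class = "Eurotiomycetes"),
    genesPerGenome = 15L,
    plants = data.frame(genome = 1L, kind = "true_resistant_bgc",
                        coreClass = "NRPS", hookId = "ALS1",
                        identityToHook = 70, outsideCopies = 1L,
                        familyLabel = "FAM_EX"),
    seed = seed)
  dir <- tempfile("exg")
  res <- generateGenomes(cfg, dir)
  on.exit(unlink(dir, recursive = TRUE))
  readGenome(res$fasta[1L], res$gff[1L],
             readTaxonTable(res$taxonTsv)[1L, ])
}
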