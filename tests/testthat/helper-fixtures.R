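suppressPackageStartupMessages({
  library(Biostrings)
  library(IRanges)
  library(GenomicRanges)
  library(S4Vectors)
})

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randProtein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# independent score oracle: Biostrings' affine-gap local aligner under the
# same matrix and gap model (gap of length k costs open + k * extend)
oracleScore <- function(a, b, scheme = scoringScheme()) {
  max(0, Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme@matrix, gapOpening = scheme@gapOpen,
    gapExtension = scheme@gapExtend, type = "local", scoreOnly = TRUE))
}

# GenomeRecord built directly from a protein table (no files); contig
# sequence is a neutral placeholder long enough to contain the genes
makeGenome <- function(assemblyId, proteins, genus = "Aspergillus",
                       klass = "Eurotiomycetes", contig = "c1",
                       spacingBp = 2000L, startAt = 1000L) {
  n <- length(proteins)
  if (n == 0L) {
    return(new("GenomeRecord", assemblyId = assemblyId,
               organism = paste(genus, "sp."), genus = genus,
               taxonomicClass = klass,
               contigs = Biostrings::DNAStringSet(setNames("ACGT", contig)),
               genes = resMiner:::.emptyGeneGR()))
  }
  lens <- nchar(proteins) * 3L + 3L
  starts <- cumsum(c(startAt, utils::head(lens + spacingBp, -1L)))
  ends <- starts + lens - 1L
  contigLen <- max(ends) + 1000L
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rep(contig, n), levels = contig),
    ranges = IRanges::IRanges(starts, ends), strand = rep("+", n),
    seqlengths = setNames(contigLen, contig))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    geneID = names(proteins), protein = unname(proteins),
    product = rep("", n),
    exons = methods::as(lapply(seq_len(n), function(i)
      IRanges::IRanges(starts[i], ends[i])), "IRangesList"))
  new("GenomeRecord", assemblyId = assemblyId,
      organism = paste(genus, "sp."), genus = genus,
      taxonomicClass = klass,
      contigs = Biostrings::DNAStringSet(setNames(
        paste(rep("A", contigLen), collapse = ""), contig)),
      genes = gr)
}

# BGCRegion over all genes of a makeGenome() genome
makeRegion <- function(genome, regionId, coreGeneIds,
                       hookHits = list(), flagged = FALSE) {
  g <- genes(genome)
  cores <- setNames(lapply(coreGeneIds, function(gid)
    new("CoreSignature", coreClass = "NRPS",
        evidence = data.frame(refId = "NRPS_ref", refClass = "NRPS",
                              score = 100L, percentIdentity = 60,
                              refCoverage = 0.9, queryStart = 1L,
                              queryEnd = 100L))), coreGeneIds)
  new("BGCRegion", regionId = regionId, assemblyId = assemblyId(genome),
      contigId = as.character(GenomicRanges::seqnames(g))[1L],
      genus = genusName(genome), taxonomicClass = taxonomicClass(genome),
      range = IRanges::IRanges(min(GenomicRanges::start(g)),
                               max(GenomicRanges::end(g))),
      genes = g, cores = cores, hookHits = hookHits, flagged = flagged)
}

hookHitFor <- function(geneId, hookId, outsideCopies, score = 500L) {
  list(hookId = hookId,
       hit = new("AlignmentHit", queryId = geneId, targetId = hookId,
                 score = as.integer(score), percentIdentity = 70,
                 queryCoverage = 0.9, targetCoverage = 0.9,
                 queryRange = c(1L, 100L), targetRange = c(1L, 100L)),
       outsideCopies = as.integer(outsideCopies))
}

# the default-conditions end-to-end run, generated and mined once per
# session and shared by pipeline and acceptance tests
.fixtureCache <- new.env(parent = emptyenv())

defaultRunFixture <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  dir <- file.path(tempdir(), sprintf("resminer_fix_%d", seed))
  sim <- generateGenomes(defaultSimConfig(seed = seed),
                         file.path(dir, "sim"))
  cfg <- runConfig(
    genomeTable = data.frame(fasta = sim$fasta, gff = sim$gff,
                             stringsAsFactors = FALSE),
    taxonTsv = sim$taxonTsv, outDir = file.path(dir, "out"), seed = seed)
  report <- runMine(cfg)
  out <- list(sim = sim, config = cfg, report = report,
              recovery = evaluateRecovery(report, sim$truth),
              outDir = file.path(dir, "out"))
  .fixtureCache[[key]] <- out
  out
}

# a one-genome configuration with one true cluster and one
# decoy_no_duplicate, used by the duplication-rule checks
leanConfig <- function(seed) simConfig(
  nGenomes = 1L,
  taxa = data.frame(genus = "Aspergillus", class = "Eurotiomycetes"),
  genesPerGenome = 10L,
  plants = data.frame(
    genome = 1L,
    kind = c("true_resistant_bgc", "decoy_no_duplicate"),
    coreClass = c("NRPS", "NR-PKS"),
    hookId = c("ALS1", "IMPDH1"),
    identityToHook = c(75, 70),
    outsideCopies = c(1L, 0L),
    familyLabel = c("T1", "D1"), stringsAsFactors = FALSE),
  seed = seed)

# controlled gene universe for family-similarity fixtures: shared ids map
# to identical proteins across regions
geneUniverse <- local({
  set.seed(400)
  setNames(vapply(1:9, function(i) randProtein(120), ""), paste0("u", 1:9))
})

regionFrom <- function(asm, rid, geneNames, genus = "Aspergillus",
                       klass = "Eurotiomycetes", coreAt = 1L,
                       hookId = "ALS1", reversed = FALSE) {
  ids <- paste0(asm, "_", geneNames)
  prots <- setNames(unname(geneUniverse[geneNames]), ids)
  if (reversed) prots <- rev(prots)
  gn <- makeGenome(asm, prots, genus = genus, klass = klass)
  reg <- makeRegion(gn, rid, coreGeneIds = ids[coreAt])
  methods::initialize(reg, hookHits = setNames(
    list(hookHitFor(ids[coreAt], hookId, 1L)), ids[coreAt]),
    flagged = TRUE)
}
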