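# hand-built FASTA + GFF3 fixtures with known translations
writeTinyGenome <- function(dir) {
  # ctgA layout:
  #   geneP: + strand, single exon 101..109  = ATGGCTTGA        -> MA
  #   geneM: - strand, single exon 201..209  = revcomp(ATGGCTTGA) -> MA
  #   geneS: + strand, exons 301..304 + 401..405 splice to ATGGCTTGA -> MA
  seqc <- paste(rep("C", 600), collapse = "")
  s <- strsplit(seqc, "")[[1]]
  ins <- function(s, at, frag) { s[at:(at + nchar(frag) - 1)] <-
    strsplit(frag, "")[[1]]; s }
  s <- ins(s, 101, "ATGGCTTGA")
  s <- ins(s, 201, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTTGA"))))
  s <- ins(s, 301, "ATGG")
  s <- ins(s, 401, "CTTGA")
  fa <- file.path(dir, "tiny.fna")
  writeLines(c(">ctgA", paste(s, collapse = "")), fa)
  gff <- file.path(dir, "tiny.gff3")
  ln <- c("##gff-version 3",
    "ctgA\tt\tgene\t101\t109\t.\t+\t.\tID=geneP",
    "ctgA\tt\tmRNA\t101\t109\t.\t+\t.\tID=geneP.t1;Parent=geneP",
    "ctgA\tt\tCDS\t101\t109\t.\t+\t0\tID=geneP.c;Parent=geneP.t1",
    "ctgA\tt\tgene\t201\t209\t.\t-\t.\tID=geneM",
    "ctgA\tt\tmRNA\t201\t209\t.\t-\t.\tID=geneM.t1;Parent=geneM",
    "ctgA\tt\tCDS\t201\t209\t.\t-\t0\tID=geneM.c;Parent=geneM.t1",
    "ctgA\tt\tgene\t301\t405\t.\t+\t.\tID=geneS",
    "ctgA\tt\tmRNA\t301\t405\t.\t+\t.\tID=geneS.t1;Parent=geneS",
    "ctgA\tt\tCDS\t301\t304\t.\t+\t0\tID=geneS.c1;Parent=geneS.t1",
    "ctgA\tt\tCDS\t401\t405\t.\t+\t2\tID=geneS.c2;Parent=geneS.t1")
  writeLines(ln, gff)
  list(fa = fa, gff = gff)
}

tinyTaxon <- list(assembly_id = "TINY", organism = "Testus tinius",
                  genus = "Testus", class = "Eurotiomycetes")

test_that("GFF3 reader translates plus, minus and spliced genes", {
  d <- withr::local_tempdir()
  f <- writeTinyGenome(d)
  gn <- readGenome(f$fa, f$gff, tinyTaxon)
  prot <- extractProteome(gn)
  expect_identical(length(prot), 3L)
  expect_identical(as.character(prot[["geneP"]]), "MA")
  expect_identical(as.character(prot[["geneM"]]), "MA")
  expect_identical(as.character(prot[["geneS"]]), "MA")
  # deterministic order: by contig then start
  expect_identical(names(prot), c("geneP", "geneM", "geneS"))
})

test_that("unknown contigs are a hard error and bad CDS lengths are skipped", {
  d <- withr::local_tempdir()
  f <- writeTinyGenome(d)
  bad <- file.path(d, "bad.gff3")
  writeLines(c(readLines(f$gff),
    "ctgZ\tt\tgene\t1\t9\t.\t+\t.\tID=ghost",
    "ctgZ\tt\tCDS\t1\t9\t.\t+\t0\tID=ghost.c;Parent=ghost"), bad)
  expect_error(readGenome(f$fa, bad, tinyTaxon), "ctgZ")

  trunc <- file.path(d, "trunc.gff3")
  writeLines(c(readLines(f$gff),
    "ctgA\tt\tgene\t501\t508\t.\t+\t.\tID=gBad",
    "ctgA\tt\tCDS\t501\t508\t.\t+\t0\tID=gBad.c;Parent=gBad"), trunc)
  expect_warning(gn <- readGenome(f$fa, trunc, tinyTaxon),
                 "not divisible by 3")
  expect_identical(nGenes(gn), 3L)   # gBad skipped
})

test_that("translation round-trips through generated genomes with introns", {
  # generator plants genes on both strands with 0-2 introns; the audit
  # pass asserts every planted protein is reproduced by the reader
  cfg <- simConfig(
    nGenomes = 1L,
    taxa = data.frame(genus = "Aspergillus", class = "Eurotiomycetes"),
    genesPerGenome = 30L,
    plants = data.frame(genome = 1L, kind = "true_resistant_bgc",
                        coreClass = "NRPS", hookId = "ALS1",
                        identityToHook = 70, outsideCopies = 1L,
                        familyLabel = "F1"),
    seed = 99L)
  d <- withr::local_tempdir()
  expect_no_error(res <- generateGenomes(cfg, d, audit = TRUE))
  gn <- readGenome(res$fasta[1], res$gff[1],
                   readTaxonTable(res$taxonTsv)[1, ])
  # both strands and at least one multi-exon gene were exercised
  expect_setequal(unique(as.character(GenomicRanges::strand(genes(gn)))),
                  c("+", "-"))
  nex <- lengths(S4Vectors::mcols(genes(gn))$exons)
  expect_true(any(nex > 1L))
})

test_that("GenBank writer re-bases coordinates and round-trips regions", {
  ex <- exampleGenome(seed = 3)
  cores <- detectCoreGenes(ex)
  regs <- assembleRegions(ex, cores)
  expect_gte(length(regs), 1L)
  pan <- builtinPanel()
  dup <- buildDuplicationIndex(ex, pan)
  reg <- resistanceScreen(regs[[1]], ex, pan, dup)

  d <- withr::local_tempdir()
  gb <- file.path(d, "region.gbk")
  writeBgcGenBank(ex, reg, gb)
  txt <- readLines(gb)
  expect_true(any(grepl("^LOCUS", txt)))
  expect_identical(sum(grepl("^     CDS ", txt)), nGenes(reg))
  # re-based coordinates: first gene appears at genomic start - region
  # start + 1
  g1 <- genes(reg)[1]
  local1 <- GenomicRanges::start(g1) - IRanges::start(regionRange(reg)) + 1L
  expect_true(any(grepl(sprintf("\\b%d\\.\\.", local1), txt)))
  # hook-hit gene carries the hook id qualifier
  if (length(hookHits(reg)))
    expect_true(any(grepl(sprintf("/hook_id=\"%s\"",
                                  hookHits(reg)[[1]]$hookId), txt)))

  back <- readGenBank(gb, list(assembly_id = "RT", organism = "o",
                               genus = "g", class = "c"))
  expect_identical(nGenes(back), nGenes(reg))
  expect_identical(geneIds(back), geneIds(reg))
  expect_identical(S4Vectors::mcols(genes(back))$protein,
                   S4Vectors::mcols(genes(reg))$protein)
})

test_that("GenBank reader agrees with the GFF3 reader on minus-strand joins", {
  d <- withr::local_tempdir()
  f <- writeTinyGenome(d)
  gn <- readGenome(f$fa, f$gff, tinyTaxon)
  seqTxt <- as.character(contigs(gn)[["ctgA"]])
  gb <- file.path(d, "tiny.gbk")
  # geneM as complement(); geneS as join(); no /translation so the reader
  # must splice and translate
  writeLines(c(
    sprintf("LOCUS       ctgA             %d bp    DNA     linear   PLN",
            nchar(seqTxt)),
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(201..209)",
    "                     /locus_tag=\"geneM\"",
    "     CDS             join(301..304,401..405)",
    "                     /locus_tag=\"geneS\"",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(substr(seqTxt, 1, 60))),
    paste(vapply(seq(61, nchar(seqTxt), 60), function(p)
      sprintf("%9d %s", p, tolower(substr(seqTxt, p, p + 59))), ""),
      collapse = "\n"),
    "//"), gb)
  gb1 <- readGenBank(gb, tinyTaxon)
  expect_identical(nGenes(gb1), 2L)
  prot <- extractProteome(gb1)
  expect_identical(as.character(prot[["geneM"]]), "MA")
  expect_identical(as.character(prot[["geneS"]]), "MA")
})

test_that("proteome extraction of an empty genome is empty", {
  gn <- makeGenome("E0", setNames(character(0), character(0)))
  expect_identical(length(extractProteome(gn)), 0L)
})
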