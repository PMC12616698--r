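coreRef <- builtinCoreReference()

test_that("core detection classifies planted genes and ignores noise", {
  nrpsRef <- as.character(coreRef$seqs[["NRPS_ref"]])
  prots <- c(core1 = mutateProtein(nrpsRef, 70, seed = 1),
             junk1 = randProtein(300, seed = 2),
             junk2 = randProtein(450, seed = 3))
  gn <- makeGenome("CD1", prots)
  calls <- detectCoreGenes(gn)
  expect_identical(names(calls), "core1")
  expect_identical(calls[["core1"]]@coreClass, "NRPS")
  expect_gte(nrow(calls[["core1"]]@evidence), 1L)
})

test_that("PKS + NRPS segment hits with low overlap call a hybrid", {
  pks <- as.character(coreRef$seqs[["HRPKS_ref"]])
  nrps <- as.character(coreRef$seqs[["NRPS_ref"]])
  fusion <- paste0(substr(pks, 1, 400), substr(nrps, 200, 640))
  gn <- makeGenome("CD2", c(fus = fusion))
  calls <- detectCoreGenes(gn, minCoverage = 0.3)
  expect_identical(calls[["fus"]]@coreClass, "PKS-NRPS")
})

test_that("region assembly windows, merging and determinism behave", {
  # 11 genes spaced 2 kb apart; core at position 6
  prots <- setNames(vapply(1:11, function(i) randProtein(100, seed = i), ""),
                    sprintf("g%02d", 1:11))
  gn <- makeGenome("RA1", prots, spacingBp = 2000L)
  coreSig <- function(ids) setNames(lapply(ids, function(gid)
    new("CoreSignature", coreClass = "NRPS",
        evidence = data.frame(refId = "NRPS_ref", refClass = "NRPS",
                              score = 100L, percentIdentity = 60,
                              refCoverage = 0.9, queryStart = 1L,
                              queryEnd = 100L))), ids)

  regs <- assembleRegions(gn, coreSig("g06"), maxIntergenes = 3L,
                          maxGapBp = 10000L)
  expect_length(regs, 1L)
  expect_identical(geneIds(regs[[1]]), sprintf("g%02d", 3:9))  # 7 genes

  # two cores 2 genes apart merge into one region
  regs2 <- assembleRegions(gn, coreSig(c("g04", "g07")),
                           maxIntergenes = 3L)
  expect_length(regs2, 1L)

  # output does not depend on the order of the core-gene list
  regs2b <- assembleRegions(gn, coreSig(c("g07", "g04")),
                            maxIntergenes = 3L)
  expect_identical(lapply(regs2, geneIds), lapply(regs2b, geneIds))
  expect_identical(vapply(regs2, regionId, ""),
                   vapply(regs2b, regionId, ""))

  # a wide bp gap stops extension
  gnW <- makeGenome("RA2", prots, spacingBp = 12000L)
  regsW <- assembleRegions(gnW, coreSig("g06"), maxIntergenes = 3L,
                           maxGapBp = 10000L)
  expect_identical(geneIds(regsW[[1]]), "g06")
})

test_that("cores on different contigs give distinct regions", {
  p1 <- c(a1 = randProtein(100, seed = 1))
  p2 <- c(b1 = randProtein(100, seed = 2))
  g1 <- makeGenome("MC1", p1, contig = "c1")
  g2 <- makeGenome("MC1", p2, contig = "c2")
  # one genome with two contigs
  gn <- new("GenomeRecord", assemblyId = "MC1", organism = "o",
            genus = "G", taxonomicClass = "K",
            contigs = c(contigs(g1), contigs(g2)),
            genes = suppressWarnings(c(genes(g1), genes(g2))))
  coreSig <- setNames(lapply(c("a1", "b1"), function(gid)
    new("CoreSignature", coreClass = "NRPS",
        evidence = data.frame(refId = "NRPS_ref", refClass = "NRPS",
                              score = 100L, percentIdentity = 60,
                              refCoverage = 0.9, queryStart = 1L,
                              queryEnd = 100L))), c("a1", "b1"))
  regs <- assembleRegions(gn, coreSig)
  expect_length(regs, 2L)
  expect_setequal(vapply(regs, function(r) r@contigId, ""), c("c1", "c2"))
})

test_that("occurrence fractions count homologue-bearing other genomes", {
  set.seed(55)
  shared <- randProtein(150)        # in all genomes
  partial <- randProtein(160)       # in 3 of 5 genomes
  unique1 <- randProtein(140)       # only in genome 1
  mk <- function(asm, withPartial) {
    prots <- c(mutateProtein(shared, 90, seed = match(asm, paste0("O", 1:5))),
               if (withPartial) mutateProtein(partial, 90,
                 seed = 10 + match(asm, paste0("O", 1:5))))
    names(prots) <- paste0(asm, "_g", seq_along(prots))
    if (asm == "O1") {
      prots <- c(prots, setNames(unique1, "O1_gu"))
    }
    makeGenome(asm, prots)
  }
  genomes <- list(mk("O1", TRUE), mk("O2", TRUE), mk("O3", TRUE),
                  mk("O4", FALSE), mk("O5", FALSE))
  occ <- buildOccurrenceIndex(genomes)
  expect_equal(unname(occ["O1_g1"]), 1.0)    # shared: 4 of 4 others
  expect_equal(unname(occ["O1_g2"]), 0.5)    # partial: 2 of 4 others
  expect_equal(unname(occ["O1_gu"]), 0.0)    # unique
  expect_error(buildOccurrenceIndex(genomes[1]), "single-genome")
})

test_that("boundary trimming removes exactly the widely distributed flanks", {
  prots <- setNames(vapply(1:7, function(i) randProtein(100, seed = i), ""),
                    paste0("t", 1:7))
  gn <- makeGenome("BT1", prots)
  reg <- makeRegion(gn, "BT1_r01", coreGeneIds = "t4")
  occ <- setNames(c(0.8, 0.1, 0.0, 0.0, 0.0, 0.1, 0.8), paste0("t", 1:7))

  trimmed <- delineateBoundaries(reg, gn, occ, cutoff = 0.5)
  expect_identical(geneIds(trimmed), paste0("t", 2:6))
  # idempotent
  again <- delineateBoundaries(trimmed, gn, occ, cutoff = 0.5)
  expect_identical(geneIds(again), geneIds(trimmed))
  # interval recomputed to the surviving genes
  expect_identical(IRanges::start(regionRange(trimmed)),
                   min(GenomicRanges::start(genes(trimmed))))

  # all genes rare: unchanged
  occLow <- setNames(rep(0.1, 7), paste0("t", 1:7))
  expect_identical(geneIds(delineateBoundaries(reg, gn, occLow)),
                   paste0("t", 1:7))

  # ubiquitous flanks are trimmed; protected genes stop trimming
  occHi <- setNames(c(1, 1, 1, 0.9, 1, 1, 1), paste0("t", 1:7))
  tHi <- delineateBoundaries(reg, gn, occHi, cutoff = 0.5)
  expect_identical(geneIds(tHi), "t4")   # core is never removed
})

test_that("the resistance screen flags only hooked regions with outside copies", {
  pan <- builtinPanel()
  hook <- as.character(hookSeqs(pan)[["ALS1"]])
  # region genes: accessory + hook homologue + core-like; an outside copy
  # beyond the region
  prots <- c(x1 = randProtein(120, seed = 1),
             x2 = mutateProtein(hook, 75, seed = 2),
             x3 = randProtein(130, seed = 3),
             far = mutateProtein(hook, 88, seed = 4))
  gn <- makeGenome("RS1", prots, spacingBp = 30000L)
  g <- genes(gn)
  idx3 <- IRanges::IRanges(GenomicRanges::start(g)[1],
                           GenomicRanges::end(g)[3])
  reg <- new("BGCRegion", regionId = "RS1_r01", assemblyId = "RS1",
             contigId = "c1", genus = "Aspergillus",
             taxonomicClass = "Eurotiomycetes", range = idx3,
             genes = g[1:3],
             cores = setNames(list(new("CoreSignature", coreClass = "NRPS",
               evidence = data.frame(refId = "r", refClass = "NRPS",
                 score = 1L, percentIdentity = 50, refCoverage = 0.8,
                 queryStart = 1L, queryEnd = 50L))), "x3"),
             hookHits = list(), flagged = FALSE)
  dup <- buildDuplicationIndex(gn, pan)
  scr <- resistanceScreen(reg, gn, pan, dup)
  expect_true(isFlagged(scr))
  expect_identical(names(hookHits(scr)), "x2")
  expect_identical(hookHits(scr)[["x2"]]$hookId, "ALS1")
  expect_identical(hookHits(scr)[["x2"]]$outsideCopies, 1L)

  # same region but the outside copy removed: hook hit, no flag
  gn2 <- makeGenome("RS2", prots[1:3], spacingBp = 30000L)
  reg2 <- methods::initialize(reg, regionId = "RS2_r01",
                              assemblyId = "RS2", genes = genes(gn2))
  dup2 <- buildDuplicationIndex(gn2, pan)
  scr2 <- resistanceScreen(reg2, gn2, pan, dup2)
  expect_false(isFlagged(scr2))
  expect_identical(hookHits(scr2)[["x2"]]$outsideCopies, 0L)

  # no hook homologue at all: no hit, no flag
  gn3 <- makeGenome("RS3", c(prots[1], prots[3]), spacingBp = 30000L)
  reg3 <- methods::initialize(reg, regionId = "RS3_r01",
                              assemblyId = "RS3", genes = genes(gn3),
                              range = IRanges::IRanges(
                                min(GenomicRanges::start(genes(gn3))),
                                max(GenomicRanges::end(genes(gn3)))))
  scr3 <- resistanceScreen(reg3, gn3, pan, buildDuplicationIndex(gn3, pan))
  expect_false(isFlagged(scr3))
  expect_length(hookHits(scr3), 0L)
})
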