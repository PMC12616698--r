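test_that("protein mutation hits the target identity exactly", {
  p <- randProtein(100, seed = 5)
  expect_identical(mutateProtein(p, 100, seed = 1), p)
  m <- mutateProtein(p, 50, seed = 2)
  diffs <- sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
  expect_identical(diffs, 50L)
  expect_identical(nchar(m), 100L)
  # deterministic under the seed, different under another
  expect_identical(mutateProtein(p, 50, seed = 2), m)
  expect_false(identical(mutateProtein(p, 50, seed = 3), m))
  expect_error(mutateProtein(p, 4, seed = 1), "below 5")
  expect_error(mutateProtein(randProtein(10, seed = 1), 80, seed = 1),
               "shorter than 20")
  # rounding: 33% of 100 -> 67 substitutions
  m33 <- mutateProtein(p, 33, seed = 4)
  expect_identical(sum(strsplit(p, "")[[1]] != strsplit(m33, "")[[1]]), 67L)
})

test_that("identical seeds give byte-identical genome files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generateGenomes(leanConfig(42L), d1, audit = FALSE)
  r2 <- generateGenomes(leanConfig(42L), d2, audit = FALSE)
  for (f in c("SYN01.fna", "SYN01.gff3", "taxa.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  r3 <- generateGenomes(leanConfig(43L), withr::local_tempdir(),
                        audit = FALSE)
  expect_false(identical(readLines(r1$fasta[1]), readLines(r3$fasta[1])))
})

test_that("emitted files satisfy the self-audit and truth invariants", {
  d <- withr::local_tempdir()
  res <- generateGenomes(leanConfig(7L), d, audit = TRUE)
  tr <- res$truth
  plants <- tr$genomes[["SYN01"]]$plants
  kinds <- vapply(plants, function(p) p$kind, "")
  expect_setequal(kinds, c("true_resistant_bgc", "decoy_no_duplicate"))
  expect_true(plants[[which(kinds == "true_resistant_bgc")]]$expectedFlag)
  expect_false(plants[[which(kinds == "decoy_no_duplicate")]]$expectedFlag)

  # truth JSON round-trips
  tr2 <- readSimTruth(res$truthJson)
  expect_identical(tr2$runId, tr$runId)
  expect_identical(length(tr2$genomes), length(tr$genomes))
})

test_that("decoy_no_duplicate plants have no outside hook copies", {
  d <- withr::local_tempdir()
  res <- generateGenomes(leanConfig(11L), d, audit = FALSE)
  gn <- readGenome(res$fasta[1], res$gff[1],
                   readTaxonTable(res$taxonTsv)[1, ])
  idx <- buildDuplicationIndex(gn, builtinPanel())
  plants <- res$truth$genomes[["SYN01"]]$plants
  decoy <- plants[[which(vapply(plants, function(p) p$kind, "") ==
                         "decoy_no_duplicate")]]
  reg <- IRanges::IRanges(decoy$start, decoy$end)
  expect_identical(
    countOutsideCopies(decoy$hookId, decoy$contig, reg, idx), 0L)
  # while the true plant's hook does have one
  tp <- plants[[which(vapply(plants, function(p) p$kind, "") ==
                      "true_resistant_bgc")]]
  expect_gte(countOutsideCopies(tp$hookId, tp$contig,
                                IRanges::IRanges(tp$start, tp$end), idx), 1L)
})

test_that("family truth labels span the planned genera", {
  cfg <- defaultSimConfig(seed = 5)
  fam <- cfg$plants[cfg$plants$familyLabel == "FAM_ALS", ]
  genera <- cfg$taxa$genus[fam$genome]
  expect_setequal(genera, c("Aspergillus", "Hypoxylon"))
})

test_that("recovery scoring arithmetic follows the declared conventions", {
  mkTruth <- function() {
    plant <- function(id, asm, s, e, flag, fam) list(
      plantId = id, kind = if (flag) "true_resistant_bgc" else
        "decoy_no_hook", familyLabel = fam, hookId = "ALS1",
      identityToHook = 70, outsideCopies = 1L, contig = "c1",
      start = s, end = e, geneIds = character(0), coreGene = "x",
      hookGene = character(0), flankGenes = character(0),
      expectedFlag = flag)
    list(runId = "fake", seed = 1, assemblies = list("A1", "A2"),
         genomes = list(
           A1 = list(assemblyId = "A1", plants = list(
             plant("p1", "A1", 1000, 2000, TRUE, "F1"),
             plant("p2", "A1", 9000, 9900, TRUE, "F1")),
             outsideCopyGenes = list(), genes = list()),
           A2 = list(assemblyId = "A2", plants = list(
             plant("p3", "A2", 1000, 2000, TRUE, "F2"),
             plant("p4", "A2", 9000, 9900, TRUE, "F2")),
             outsideCopyGenes = list(), genes = list())))
  }
  fakeRegion <- function(asm, rid, s, e) {
    gn <- makeGenome(asm, setNames(randProtein(60, seed = nchar(rid)),
                                   paste0(rid, "_g1")), startAt = s + 10L)
    reg <- makeRegion(gn, rid, coreGeneIds = paste0(rid, "_g1"),
                      hookHits = setNames(list(
                        hookHitFor(paste0(rid, "_g1"), "ALS1", 1L)),
                        paste0(rid, "_g1")),
                      flagged = TRUE)
    methods::initialize(reg, range = IRanges::IRanges(s, e))
  }
  # flags 3 of 4 positives plus 1 off-target region
  out <- list(flaggedRegions = list(
    fakeRegion("A1", "r1", 900, 2100),
    fakeRegion("A1", "r2", 8950, 9800),
    fakeRegion("A2", "r3", 950, 2050),
    fakeRegion("A2", "rX", 50000, 51000)),
    familiesRefined = list())
  ev <- evaluateRecovery(out, mkTruth())
  expect_equal(ev$flagRecall, 0.75)
  expect_equal(ev$flagPrecision, 0.75)

  # nothing flagged: precision reported as 1 with a notice
  ev0 <- evaluateRecovery(list(flaggedRegions = list(),
                               familiesRefined = list()), mkTruth())
  expect_equal(ev0$flagRecall, 0)
  expect_equal(ev0$flagPrecision, 1)
  expect_match(ev0$notices, "no regions flagged", all = FALSE)

  # an assembly unknown to the truth is a mismatched run
  bad <- list(flaggedRegions = list(fakeRegion("ZZ", "rz", 1, 500)),
              familiesRefined = list())
  expect_error(evaluateRecovery(bad, mkTruth()), "mismatched")
})
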