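# region fixtures (geneUniverse / regionFrom) come from the helpers

test_that("similarity of a region with itself is 1 and disjoint is 0", {
  a <- regionFrom("SA", "SA_r1", c("u1", "u2", "u3", "u4"))
  s <- bgcSimilarity(a, a)
  expect_equal(s@combined, 1.0)
  expect_equal(s@jaccard, 1.0)
  expect_equal(s@adjacency, 1.0)
  expect_equal(s@identity, 1.0)

  b <- regionFrom("SB", "SB_r1", c("u5", "u6", "u7"))
  s0 <- bgcSimilarity(a, b)
  expect_equal(s0@combined, 0.0)
})

test_that("gene-order reversal leaves unordered adjacency intact", {
  a <- regionFrom("RA", "RA_r1", c("u1", "u2", "u3", "u4"))
  b <- regionFrom("RB", "RB_r1", c("u1", "u2", "u3", "u4"),
                  reversed = TRUE, coreAt = 4L)
  s <- bgcSimilarity(a, b)
  expect_equal(s@jaccard, 1.0)
  expect_equal(s@adjacency, 1.0)
  expect_equal(s@identity, 1.0)
  expect_equal(s@combined, 1.0)
})

test_that("single-linkage chains regions through shared neighbours", {
  a <- regionFrom("CA", "CA_r1", c("u1", "u2", "u3", "u4"))
  b <- regionFrom("CB", "CB_r1", c("u2", "u3", "u4", "u5", "u6", "u7"),
                  coreAt = 1L)
  c3 <- regionFrom("CC", "CC_r1", c("u5", "u6", "u7", "u8"))
  sab <- bgcSimilarity(a, b)@combined
  sbc <- bgcSimilarity(b, c3)@combined
  sac <- bgcSimilarity(a, c3)@combined
  expect_gte(sab, 0.7)
  expect_gte(sbc, 0.7)
  expect_lt(sac, 0.3)
  fams <- clusterFamilies(list(a, b, c3), cutoff = 0.3)
  expect_length(fams, 1L)
  expect_setequal(vapply(members(fams[[1]]), regionId, ""),
                  c("CA_r1", "CB_r1", "CC_r1"))

  # all pairwise similarity below the joining threshold: singletons
  d <- regionFrom("CD", "CD_r1", c("u8", "u9"))
  famsLow <- clusterFamilies(list(a, c3, d), cutoff = 0.3)
  expect_length(famsLow, 3L)
})

test_that("family clustering is invariant under input permutation", {
  a <- regionFrom("PA", "PA_r1", c("u1", "u2", "u3", "u4"))
  b <- regionFrom("PB", "PB_r1", c("u1", "u2", "u3", "u5"))
  c3 <- regionFrom("PC", "PC_r1", c("u6", "u7", "u8"))
  f1 <- clusterFamilies(list(a, b, c3))
  f2 <- clusterFamilies(list(c3, b, a))
  expect_identical(vapply(f1, familyId, ""), vapply(f2, familyId, ""))
  expect_identical(lapply(f1, function(f)
    sort(vapply(members(f), regionId, ""))),
    lapply(f2, function(f) sort(vapply(members(f), regionId, ""))))
})

test_that("refinement splits on core signature and on hook, idempotently", {
  mkMember <- function(asm, core, hook) {
    reg <- regionFrom(asm, paste0(asm, "_r1"), c("u1", "u2", "u3"),
                      hookId = hook)
    cores <- setNames(list(new("CoreSignature", coreClass = core,
      evidence = data.frame(refId = "r", refClass = core, score = 1L,
        percentIdentity = 50, refCoverage = 0.8, queryStart = 1L,
        queryEnd = 50L))), names(coreCalls(reg)))
    methods::initialize(reg, cores = cores)
  }
  fam <- new("Family", familyId = "F001",
             members = list(mkMember("MA", "NRPS", "ALS1"),
                            mkMember("MB", "HR-PKS", "ALS1"),
                            mkMember("MC", "NRPS", "IMPDH1"),
                            mkMember("MD", "NRPS", "ALS1")),
             coreSignature = character(0), hookSignature = "",
             genera = "Aspergillus",
             classCounts = c(Eurotiomycetes = 4L))
  ref <- refineFamilies(list(fam))
  expect_length(ref, 3L)
  key <- vapply(ref, function(f)
    paste(paste(coreSignature(f), collapse = "+"), hookSignature(f)), "")
  expect_setequal(key, c("NRPS ALS1", "HR-PKS ALS1", "NRPS IMPDH1"))
  sizes <- vapply(ref, function(f) length(members(f)), 0L)
  expect_identical(sum(sizes), 4L)    # never merges, never loses members

  # idempotent: refining refined families changes nothing
  ref2 <- refineFamilies(ref)
  expect_identical(vapply(ref2, familyId, ""), vapply(ref, familyId, ""))
  expect_identical(lapply(ref2, function(f)
    sort(vapply(members(f), regionId, ""))),
    lapply(ref, function(f) sort(vapply(members(f), regionId, ""))))

  # a homogeneous family passes through unchanged
  homog <- new("Family", familyId = "F001",
               members = list(mkMember("ME", "NRPS", "ALS1"),
                              mkMember("MF", "NRPS", "ALS1")),
               coreSignature = "NRPS", hookSignature = "ALS1",
               genera = "Aspergillus", classCounts = c(Eurotiomycetes = 2L))
  expect_length(refineFamilies(list(homog)), 1L)
})

test_that("single-genus families are dropped, multi-genus kept", {
  asp <- regionFrom("GA", "GA_r1", c("u1", "u2"), genus = "Aspergillus")
  asp2 <- regionFrom("GB", "GB_r1", c("u1", "u2"), genus = "Aspergillus")
  hyp <- regionFrom("GC", "GC_r1", c("u1", "u2"), genus = "Hypoxylon",
                    klass = "Sordariomycetes")
  single <- new("Family", familyId = "F001", members = list(asp, asp2),
                coreSignature = "NRPS", hookSignature = "ALS1",
                genera = "Aspergillus", classCounts = c(Eurotiomycetes = 2L))
  multi <- new("Family", familyId = "F002", members = list(asp, hyp),
               coreSignature = "NRPS", hookSignature = "ALS1",
               genera = c("Aspergillus", "Hypoxylon"),
               classCounts = c(Eurotiomycetes = 1L, Sordariomycetes = 1L))
  kept <- dropSingleGenus(list(single, multi))
  expect_length(kept, 1L)
  expect_identical(familyId(kept[[1]]), "F002")
  expect_length(dropSingleGenus(list(single)), 0L)
})

test_that("taxonomy summary counts are conserved", {
  mk <- function(asm, klass) regionFrom(asm, paste0(asm, "_r1"),
    c("u1", "u2"), genus = asm, klass = klass)
  sords <- lapply(paste0("S", 1:4), mk, klass = "Sordariomycetes")
  euros <- lapply(paste0("E", 1:2), mk, klass = "Eurotiomycetes")
  fam1 <- new("Family", familyId = "F001", members = sords,
              coreSignature = "NRPS", hookSignature = "ALS1",
              genera = paste0("S", 1:4),
              classCounts = c(Sordariomycetes = 4L))
  fam2 <- new("Family", familyId = "F002", members = euros,
              coreSignature = "NRPS", hookSignature = "ALS1",
              genera = paste0("E", 1:2),
              classCounts = c(Eurotiomycetes = 2L))
  tx <- taxonomySummary(list(fam1, fam2))
  expect_identical(unname(tx$classTotals["Sordariomycetes"]), 4)
  expect_identical(unname(tx$classTotals["Eurotiomycetes"]), 2)
  expect_identical(sum(tx$classTotals), 6)
  expect_identical(tx$byFamily$family_id, c("F001", "F002"))

  one <- taxonomySummary(list(fam1))
  expect_identical(sum(one$classTotals), 4)
})
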