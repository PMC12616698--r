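test_that("local alignment recovers exact-match scores and identities", {
  h <- smithWaterman("ACDE", "ACDE")
  expect_s4_class(h, "AlignmentHit")
  # sum of BLOSUM62 diagonal entries: A 4, C 9, D 6, E 5
  expect_identical(h@score, 24L)
  expect_equal(h@percentIdentity, 100)
  expect_equal(h@queryCoverage, 1)
  expect_equal(h@targetCoverage, 1)
})

test_that("all-negative substitution pairs yield no alignment", {
  expect_null(smithWaterman("AAAA", "WWWW"))
})

test_that("illegal residues are rejected with their position", {
  expect_error(smithWaterman("ACDB", "ACDE"), "position 4")
  expect_error(smithWaterman("AC1E", "ACDE"), "position 3")
})

test_that("X scores zero against every residue", {
  h <- smithWaterman("AXA", "AAA")
  expect_identical(h@score, 8L)   # 4 + 0 + 4
  sch <- scoringScheme()
  expect_true(all(sch@matrix["X", ] == 0))
  expect_true(all(sch@matrix[, "X"] == 0))
})

test_that("score is symmetric and self-identity is 100", {
  sch <- scoringScheme()
  set.seed(11)
  for (i in 1:40) {
    a <- randProtein(sample(5:60, 1))
    b <- randProtein(sample(5:60, 1))
    ha <- smithWaterman(a, b, sch)
    hb <- smithWaterman(b, a, sch)
    sa <- if (is.null(ha)) 0L else ha@score
    sb <- if (is.null(hb)) 0L else hb@score
    expect_identical(sa, sb)
    self <- smithWaterman(a, a, sch)
    expect_equal(self@percentIdentity, 100)
  }
})

test_that("engine agrees with the independent affine-gap oracle", {
  sch <- scoringScheme()
  set.seed(7)
  for (i in 1:60) {
    a <- randProtein(sample(5:40, 1))
    b <- if (i %% 3 == 0) {
      ch <- strsplit(a, "")[[1]]
      paste(ch[-sample(length(ch), sample(1:3, 1))], collapse = "")
    } else randProtein(sample(5:40, 1))
    h <- smithWaterman(a, b, sch)
    expect_identical(if (is.null(h)) 0 else as.numeric(h@score),
                     oracleScore(a, b, sch))
  }
})

test_that("BLOSUM45 scheme is loadable and gap invariants hold", {
  sch <- scoringScheme("BLOSUM45", gapOpen = 14, gapExtend = 2)
  expect_identical(sch@matrixName, "BLOSUM45")
  expect_error(scoringScheme(gapOpen = 1, gapExtend = 3))
  h <- smithWaterman("ACDE", "ACDE", sch)
  expect_equal(h@percentIdentity, 100)
})

test_that("panel search returns the best qualifying hook with ties by id", {
  set.seed(21)
  q <- randProtein(120)
  hookA <- q                                  # identical: best
  hookB <- mutateProtein(q, 60, seed = 3)     # qualifying but weaker
  hookC <- randProtein(120)                   # unrelated
  pan <- resMiner:::.newPanel("t", c("HK_A", "HK_B", "HK_C"),
    c(hookA, hookB, hookC),
    list(sourceLocus = c("l1", "l2", "l3"),
         category = rep("housekeeping", 3), annotation = rep("", 3)))
  hit <- searchPanel(q, pan)
  expect_identical(hit@targetId, "HK_A")
  expect_equal(hit@percentIdentity, 100)

  # a generator-mutated pair at 45% identity misses a 50% threshold
  hookLong <- randProtein(300, seed = 8)
  far <- mutateProtein(hookLong, 45, seed = 5)
  panFar <- resMiner:::.newPanel("t2", "HK_L", hookLong,
    list(sourceLocus = "l2", category = "housekeeping", annotation = ""))
  expect_null(searchPanel(far, panFar, minIdentity = 50, minCoverage = 0.7))
  # ... and passes once the threshold drops below its identity
  expect_s4_class(searchPanel(far, panFar, minIdentity = 35,
                              minCoverage = 0.5), "AlignmentHit")

  # two qualifying hooks: higher score wins
  pan2 <- resMiner:::.newPanel("t3", c("HK_A", "HK_B"), c(hookA, hookB),
    list(sourceLocus = c("l1", "l2"), category = rep("housekeeping", 2),
         annotation = rep("", 2)))
  expect_identical(searchPanel(q, pan2)@targetId, "HK_A")
})

test_that("raising the identity threshold never adds panel hits", {
  set.seed(33)
  pan <- builtinPanel()
  queries <- c(
    lapply(1:6, function(i) randProtein(150)),
    lapply(hookIds(pan)[1:4], function(h)
      mutateProtein(as.character(hookSeqs(pan)[[h]]), 55 + 5 * match(h, hookIds(pan)),
                    seed = match(h, hookIds(pan)))))
  hits <- function(minId) sum(vapply(queries, function(q)
    !is.null(searchPanel(q, pan, minIdentity = minId)), TRUE))
  counts <- vapply(c(30, 50, 70, 90), hits, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("duplication index lists planted copies and outside counting works", {
  pan <- builtinPanel()
  hook <- as.character(hookSeqs(pan)[["ALS1"]])
  prots <- c(
    g1 = randProtein(150, seed = 1),
    g2 = mutateProtein(hook, 85, seed = 2),   # in-region copy
    g3 = randProtein(200, seed = 3),
    g4 = mutateProtein(hook, 88, seed = 4),   # outside copy
    g5 = mutateProtein(hook, 90, seed = 5))   # outside copy
  gn <- makeGenome("ASM1", prots)
  idx <- buildDuplicationIndex(gn, pan)
  expect_identical(sort(idx[["ALS1"]]$geneId), c("g2", "g4", "g5"))
  expect_true(all(vapply(setdiff(names(idx), "ALS1"),
                         function(h) nrow(idx[[h]]) == 0L, TRUE)))
  # scores sorted descending
  expect_false(is.unsorted(rev(idx[["ALS1"]]$score)))

  g <- genes(gn)
  reg <- IRanges::IRanges(GenomicRanges::start(g)[1],
                          GenomicRanges::end(g)[2])  # covers g1..g2
  expect_identical(countOutsideCopies("ALS1", "c1", reg, idx), 2L)
  allR <- IRanges::IRanges(min(GenomicRanges::start(g)),
                           max(GenomicRanges::end(g)))
  expect_identical(countOutsideCopies("ALS1", "c1", allR, idx), 0L)
  expect_identical(countOutsideCopies("ALS1", "other_contig", allR, idx), 3L)
  expect_identical(countOutsideCopies("NOHOOK", "c1", reg, idx), 0L)
})

test_that("genome without hook homologues yields an empty index", {
  gn <- makeGenome("ASM2", c(a = randProtein(100, seed = 9),
                             b = randProtein(120, seed = 10)))
  idx <- buildDuplicationIndex(gn, builtinPanel())
  expect_true(all(vapply(idx, nrow, 0L) == 0L))
})
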