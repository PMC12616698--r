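.PLANT_KINDS <- c("true_resistant_bgc", "decoy_no_duplicate",
                  "decoy_no_hook", "decoy_duplicate_outside_only")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run expr under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.randProtein <- function(len) paste(sample(.AA20, len, replace = TRUE),
                                    collapse = "")
.randDna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

#' Mutate a protein to a target identity
#'
#' Substitutes exactly `round((1 - targetIdentity/100) * L)` positions,
#' chosen uniformly without replacement, each to a residue different from
#' the one it replaces, so the realized identity equals the target within
#' rounding. Deterministic for a given seed.
#'
#' @param sequence amino-acid string (length >= 20)
#' @param targetIdentity percent identity to aim for (must exceed 5)
#' @param seed integer seed
#' @return the mutated sequence (character)
#' @examples
#' p <- paste(rep("ACDEFGHIKL", 10), collapse = "")
#' m <- mutateProtein(p, 50, seed = 7)
#' mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])  # 0.5
#' @export
mutateProtein <- function(sequence, targetIdentity, seed) {
  L <- nchar(sequence)
  if (L < 20L) stop("sequence shorter than 20 residues")
  if (targetIdentity <= 5)
    stop("target identity below 5% is meaningless")
  if (targetIdentity > 100) stop("target identity above 100%")
  nSub <- round((1 - targetIdentity / 100) * L)
  if (nSub == 0L) return(sequence)
  .withSeed(seed, {
    pos <- sample.int(L, nSub)
    chars <- strsplit(sequence, "")[[1]]
    for (p in pos)
      chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
    paste(chars, collapse = "")
  })
}

#' Specify a synthetic multi-genome simulation
#'
#' Defines the genomes to emit and the features to plant in them. `plants`
#' takes one row per planted cluster with columns:
#' \describe{
#'   \item{genome}{index of the receiving genome}
#'   \item{kind}{one of `true_resistant_bgc`, `decoy_no_duplicate`,
#'     `decoy_no_hook`, `decoy_duplicate_outside_only`}
#'   \item{coreClass}{core-enzyme class of the planted cluster}
#'   \item{hookId}{hook the planted resistance gene derives from}
#'   \item{identityToHook}{percent identity of the planted in-cluster hook
#'     homologue to the hook}
#'   \item{outsideCopies}{number of intact housekeeping copies planted
#'     outside the cluster (on a second contig)}
#'   \item{familyLabel}{truth family label; plants sharing a label across
#'     genomes are homologous clusters built from one template}
#' }
#' Optional columns `conservedFlanks` (genes added on each side of the
#' cluster, default 0) and `flankOccurrence` (fraction of the other genomes
#' receiving a homologue of each flank gene, default 0.8) exercise boundary
#' delineation.
#'
#' @param nGenomes number of genomes
#' @param taxa data.frame with `genus` and `class`, one row per genome
#' @param genesPerGenome number of background genes per genome
#' @param plants plant plan data.frame (see Details)
#' @param seed integer seed fixing all randomness
#' @param bgConservedFraction fraction of background genes drawn from a
#'   pool shared across all genomes (each genome carries a copy mutated to
#'   88 percent identity), emulating the widely distributed housekeeping
#'   complement of real genomes; the rest are genome-unique (default 0.5)
#' @param panel the [HookPanel-class] hooks derive from (default
#'   [builtinPanel()])
#' @param coreRef core reference set (default [builtinCoreReference()])
#' @return a validated `SimConfig` list
#' @seealso [defaultSimConfig()], [generateGenomes()]
#' @export
simConfig <- function(nGenomes, taxa, genesPerGenome, plants, seed,
                      bgConservedFraction = 0.5,
                      panel = builtinPanel(),
                      coreRef = builtinCoreReference()) {
  stopifnot(bgConservedFraction >= 0, bgConservedFraction <= 1)
  stopifnot(nGenomes >= 1L, nrow(taxa) == nGenomes,
            all(c("genus", "class") %in% colnames(taxa)))
  if (is.null(plants$conservedFlanks)) plants$conservedFlanks <- 0L
  if (is.null(plants$flankOccurrence)) plants$flankOccurrence <- 0.8
  need <- c("genome", "kind", "coreClass", "hookId", "identityToHook",
            "outsideCopies", "familyLabel")
  miss <- setdiff(need, colnames(plants))
  if (length(miss))
    stop("plant plan lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(plants$kind %in% .PLANT_KINDS))
    stop("unknown plant kind(s): ",
         paste(setdiff(plants$kind, .PLANT_KINDS), collapse = ", "))
  if (any(plants$genome < 1L | plants$genome > nGenomes))
    stop("plant assigned to a genome outside 1..nGenomes")
  bad <- plants$kind == "true_resistant_bgc" & plants$outsideCopies < 1L
  if (any(bad)) stop("true_resistant_bgc requires outsideCopies >= 1")
  bad <- plants$kind == "decoy_no_duplicate" & plants$outsideCopies != 0L
  if (any(bad)) stop("decoy_no_duplicate requires outsideCopies == 0")
  if (!all(plants$hookId %in% hookIds(panel)))
    stop("plant hook(s) not in panel: ",
         paste(setdiff(plants$hookId, hookIds(panel)), collapse = ", "))
  if (!all(plants$coreClass %in% coreRef$class))
    stop("plant core class(es) without reference: ",
         paste(setdiff(plants$coreClass, coreRef$class), collapse = ", "))
  # a decoy_no_duplicate hook must not gain outside copies from another
  # plant in the same genome, or its truth label would be wrong
  for (g in unique(plants$genome)) {
    pg <- plants[plants$genome == g, ]
    noDup <- pg$hookId[pg$kind == "decoy_no_duplicate"]
    withCopies <- pg$hookId[pg$outsideCopies > 0L]
    clash <- intersect(noDup, withCopies)
    if (length(clash))
      stop("genome ", g, ": hook(s) ", paste(clash, collapse = ", "),
           " used by decoy_no_duplicate but planted with outside copies")
  }
  # members of one family must agree on kind, core, hook and identity
  for (fl in unique(plants$familyLabel)) {
    pf <- plants[plants$familyLabel == fl, ]
    if (nrow(unique(pf[, c("kind", "coreClass", "hookId",
                           "identityToHook")])) != 1L)
      stop("family '", fl, "': members disagree on kind/core/hook/identity")
  }
  structure(list(nGenomes = as.integer(nGenomes), taxa = taxa,
                 genesPerGenome = as.integer(genesPerGenome),
                 bgConservedFraction = bgConservedFraction,
                 plants = plants, seed = as.integer(seed), panel = panel,
                 coreRef = coreRef),
            class = "SimConfig")
}

#' The default synthetic study conditions
#'
#' Five genomes in two genera (three *Aspergillus*, Eurotiomycetes; two
#' *Hypoxylon*, Sordariomycetes), four true resistant BGCs at 65-80 percent
#' hook identity forming two truth families (one spanning both genera, one
#' confined to *Aspergillus*), and three decoys of each decoy kind. This is
#' the configuration exercised by the benchmark suite.
#'
#' @param seed integer seed (default 1)
#' @param genesPerGenome background genes per genome (default 40)
#' @return a `SimConfig`
#' @export
defaultSimConfig <- function(seed = 1L, genesPerGenome = 40L) {
  taxa <- data.frame(
    genus = c("Aspergillus", "Aspergillus", "Aspergillus",
              "Hypoxylon", "Hypoxylon"),
    class = c("Eurotiomycetes", "Eurotiomycetes", "Eurotiomycetes",
              "Sordariomycetes", "Sordariomycetes"),
    stringsAsFactors = FALSE)
  plants <- rbind(
    # two-genus truth family (survives the genus filter)
    data.frame(genome = 1L, kind = "true_resistant_bgc", coreClass = "NRPS",
               hookId = "ALS1", identityToHook = 75, outsideCopies = 1L,
               familyLabel = "FAM_ALS"),
    data.frame(genome = 4L, kind = "true_resistant_bgc", coreClass = "NRPS",
               hookId = "ALS1", identityToHook = 75, outsideCopies = 1L,
               familyLabel = "FAM_ALS"),
    # single-genus truth family (dropped by the genus filter)
    data.frame(genome = 2L, kind = "true_resistant_bgc",
               coreClass = "HR-PKS", hookId = "IMPDH1",
               identityToHook = 70, outsideCopies = 1L,
               familyLabel = "FAM_IMP"),
    data.frame(genome = 3L, kind = "true_resistant_bgc",
               coreClass = "HR-PKS", hookId = "IMPDH1",
               identityToHook = 70, outsideCopies = 1L,
               familyLabel = "FAM_IMP"),
    # three decoys per decoy kind
    data.frame(genome = c(1L, 3L, 5L), kind = "decoy_no_duplicate",
               coreClass = c("NR-PKS", "terpene_synthase", "NRPS-like"),
               hookId = c("HMGR1", "ADSS1", "PSMB1"),
               identityToHook = c(70, 65, 72), outsideCopies = 0L,
               familyLabel = c("DND1", "DND2", "DND3")),
    data.frame(genome = c(2L, 4L, 5L), kind = "decoy_no_hook",
               coreClass = c("prenyltransferase", "NRPS", "NR-PKS"),
               hookId = "ALS1", identityToHook = 70, outsideCopies = 0L,
               familyLabel = c("DNH1", "DNH2", "DNH3")),
    data.frame(genome = c(1L, 2L, 5L), kind = "decoy_duplicate_outside_only",
               coreClass = c("terpene_synthase", "NRPS-like",
                             "prenyltransferase"),
               hookId = c("DAHP1", "SUR2", "TUBB1"),
               identityToHook = c(80, 70, 68), outsideCopies = 2L,
               familyLabel = c("DDO1", "DDO2", "DDO3")))
  simConfig(nGenomes = 5L, taxa = taxa, genesPerGenome = genesPerGenome,
            plants = plants, seed = seed)
}

# --- reverse translation and gene layout ----------------------------------

.CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.reverseTranslate <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- .CODONS[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  stop <- .CODONS[["*"]][sample.int(3L, 1L)]
  paste(c(codons, stop), collapse = "")
}

# build the genomic fragment of one gene: returns list(frag, exonsLocal,
# strand) where exonsLocal are CDS intervals within frag, genomic order
.geneFragment <- function(protein, strand, nIntrons = 0L) {
  cds <- .reverseTranslate(protein)
  L <- nchar(cds)
  if (nIntrons > 0L && L > 60L) {
    cuts <- sort(sample(seq.int(10L, L - 10L), nIntrons))
    segs <- substring(cds, c(1L, cuts + 1L), c(cuts, L))
    introns <- vapply(seq_len(nIntrons),
                      function(i) .randDna(sample(60:150, 1L)), "")
    frag <- segs[1L]
    exons <- list(c(1L, nchar(segs[1L])))
    for (i in seq_len(nIntrons)) {
      frag <- paste0(frag, introns[i])
      s <- nchar(frag) + 1L
      frag <- paste0(frag, segs[i + 1L])
      exons <- c(exons, list(c(s, nchar(frag))))
    }
  } else {
    frag <- cds
    exons <- list(c(1L, L))
  }
  fragLen <- nchar(frag)
  if (strand == "-") {
    frag <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(frag)))
    exons <- rev(lapply(exons, function(e)
      c(fragLen - e[2L] + 1L, fragLen - e[1L] + 1L)))
  }
  list(frag = frag, exons = exons, strand = strand)
}

# transcript-order phases for the genomic-order exon list of one gene
.exonPhases <- function(exons, strand) {
  lens <- vapply(exons, function(e) e[2L] - e[1L] + 1L, 0L)
  txLens <- if (strand == "-") rev(lens) else lens
  cum <- c(0L, cumsum(txLens))[seq_along(txLens)]
  ph <- (3L - cum %% 3L) %% 3L
  if (strand == "-") rev(ph) else ph
}

# --- genome generation ----------------------------------------------------

.gffEscape <- function(x) gsub("[;=,\t]", "_", x)

.writeGff3 <- function(entries, contigLens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ctg in names(contigLens))
    writeLines(sprintf("##sequence-region %s 1 %d", ctg, contigLens[[ctg]]),
               con)
  for (e in entries) {
    at <- function(s, en, type, ph, attrs)
      writeLines(paste(e$contig, "resMinerSim", type, s, en, ".", e$strand,
                       ph, attrs, sep = "\t"), con)
    gs <- e$start; ge <- e$end
    at(gs, ge, "gene", ".", sprintf("ID=%s", e$id))
    at(gs, ge, "mRNA", ".",
       sprintf("ID=%s.t1;Parent=%s;product=%s", e$id, e$id,
               .gffEscape(e$product)))
    ph <- .exonPhases(e$exons, e$strand)
    for (k in seq_along(e$exons))
      at(e$exons[[k]][1L], e$exons[[k]][2L], "CDS", ph[k],
         sprintf("ID=%s.cds;Parent=%s.t1", e$id, e$id))
  }
  invisible(path)
}

#' Generate synthetic genomes with planted clusters and ground truth
#'
#' Emits one FASTA + GFF3 pair per genome, a taxon metadata TSV and a
#' ground-truth JSON. Background genes are random ORFs (no introns);
#' planted genes are reverse-translated with uniformly random synonymous
#' codons and may carry 0-2 introns to exercise splicing. Each planted
#' cluster places its core gene (mutated from the core reference at ~70
#' percent identity), an in-cluster hook homologue at the plant's
#' `identityToHook` (except `decoy_no_hook`), and accessory genes; plants
#' sharing a `familyLabel` are derived from one family template (members at
#' 96 percent of the template) so they form a recoverable family. Intact
#' outside housekeeping copies (88 percent identity to the hook) go on a
#' second contig. All randomness is fixed by `config$seed`; identical
#' configs yield byte-identical files.
#'
#' A self-audit re-reads every emitted genome through [readGenome()] and
#' verifies the planted proteins at their truth coordinates.
#'
#' @param config a `SimConfig` from [simConfig()]
#' @param outDir output directory (created if needed)
#' @param audit run the self-audit pass (default TRUE)
#' @return invisible list: `fasta`, `gff` (paths per genome), `taxonTsv`,
#'   `truthJson`, and `truth` (the in-memory `SimTruth` list)
#' @export
generateGenomes <- function(config, outDir, audit = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  panel <- config$panel; coreRef <- config$coreRef
  plants <- config$plants
  nG <- config$nGenomes
  asmIds <- sprintf("SYN%02d", seq_len(nG))

  .withSeed(config$seed, {
    nextSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)

    # family templates, in first-appearance order
    tmpl <- list()
    for (fl in unique(plants$familyLabel)) {
      p <- plants[plants$familyLabel == fl, ][1L, ]
      refSeq <- as.character(
        coreRef$seqs[[names(coreRef$class)[coreRef$class == p$coreClass][1L]]])
      t <- list(core = mutateProtein(refSeq, 70, nextSeed()))
      # only these kinds carry a hook homologue inside the cluster; the
      # outside-duplicate-only decoy has intact copies but no cluster copy
      if (p$kind %in% c("true_resistant_bgc", "decoy_no_duplicate"))
        t$hook <- mutateProtein(as.character(hookSeqs(panel)[[p$hookId]]),
                                p$identityToHook, nextSeed())
      t$acc <- vapply(1:3, function(i) .randProtein(sample(200:400, 1L)), "")
      if (p$conservedFlanks > 0L)
        t$flanks <- vapply(seq_len(p$conservedFlanks),
                           function(i) .randProtein(sample(250:350, 1L)), "")
      tmpl[[fl]] <- t
    }

    # per-genome rosters: background entries + cluster blocks
    mkGene <- function(protein, product, role, nIntrons = 0L) {
      strand <- sample(c("+", "-"), 1L)
      fr <- .geneFragment(protein, strand, nIntrons)
      list(protein = protein, product = product, role = role,
           frag = fr$frag, exonsLocal = fr$exons, strand = strand)
    }

    blocks <- vector("list", nG)      # cluster blocks per genome
    extraBg <- vector("list", nG)     # planted background-like homologues
    contig2 <- vector("list", nG)     # outside duplicates

    for (pi in seq_len(nrow(plants))) {
      p <- plants[pi, ]
      fl <- p$familyLabel
      t <- tmpl[[fl]]
      multi <- sum(plants$familyLabel == fl) > 1L
      derive <- function(seqc)
        if (multi) mutateProtein(seqc, 96, nextSeed()) else seqc
      core <- mkGene(derive(t$core),
                     sprintf("%s core enzyme", p$coreClass), "core",
                     sample(0:2, 1L))
      accs <- lapply(t$acc, function(a)
        mkGene(derive(a), "hypothetical protein", "accessory",
               sample(0:2, 1L)))
      cluster <- list(accs[[1L]])
      hookGene <- NULL
      if (!is.null(t$hook)) {
        ann <- hookMeta(panel)$annotation[match(p$hookId,
                                                hookIds(panel))]
        hookGene <- mkGene(derive(t$hook),
                           sprintf("%s, cluster-associated", ann),
                           "hook", sample(0:2, 1L))
        cluster <- c(cluster, list(hookGene))
      }
      cluster <- c(cluster, list(core), lapply(accs[2:3], identity))
      flanks <- list()
      if (!is.null(t$flanks)) {
        flanks <- lapply(t$flanks, function(f)
          mkGene(derive(f), "conserved hypothetical protein", "flank"))
        # plant flank homologues as background genes in other genomes
        nOther <- round(p$flankOccurrence * (nG - 1L))
        others <- setdiff(seq_len(nG), p$genome)
        recv <- others[seq_len(min(nOther, length(others)))]
        for (g in recv) for (f in t$flanks)
          extraBg[[g]] <- c(extraBg[[g]], list(
            mkGene(mutateProtein(f, 90, nextSeed()),
                   "conserved hypothetical protein", "flank_homolog")))
      }
      blocks[[p$genome]] <- c(blocks[[p$genome]], list(list(
        plantRow = pi, cluster = cluster, flanks = flanks)))
      if (p$outsideCopies > 0L) {
        ann <- hookMeta(panel)$annotation[match(p$hookId, hookIds(panel))]
        for (k in seq_len(p$outsideCopies))
          contig2[[p$genome]] <- c(contig2[[p$genome]], list(
            mkGene(mutateProtein(
              as.character(hookSeqs(panel)[[p$hookId]]), 88, nextSeed()),
              ann, "outside_copy")))
      }
    }

    # conserved background pool shared by every genome
    nPool <- round(config$bgConservedFraction * config$genesPerGenome)
    pool <- if (nPool) vapply(seq_len(nPool), function(i)
      .randProtein(sample(99:499, 1L)), "") else character(0)

    # lay out each genome and write files
    fastaPaths <- gffPaths <- character(nG)
    truthGenomes <- list()
    taxaRows <- list()
    for (g in seq_len(nG)) {
      asm <- asmIds[g]
      nUnique <- config$genesPerGenome - nPool
      bg <- c(
        lapply(pool, function(pp)
          mkGene(mutateProtein(pp, 88, nextSeed()),
                 "conserved hypothetical protein", "background_conserved")),
        lapply(seq_len(nUnique), function(i)
          mkGene(.randProtein(sample(99:499, 1L)), "hypothetical protein",
                 "background")))
      bg <- bg[sample.int(length(bg))]
      bg <- c(bg, extraBg[[g]])
      nB <- length(bg)
      K <- length(blocks[[g]] %||% list())
      # keep planted clusters >= 10 background genes apart so the default
      # assembly windows (4 genes each side) cannot fuse two plants
      ins <- integer(0)
      if (K) {
        for (try in 1:200) {
          cand <- sort(sample.int(nB + 1L, K) - 1L)
          if (K == 1L || min(diff(cand)) >= 10L) { ins <- cand; break }
        }
        if (!length(ins)) ins <- round(seq(2, nB - 2, length.out = K))
      }

      geneCounter <- 0L
      layoutContig <- function(items, ctgName, clusterGap = FALSE) {
        # items: list of list(gene=..., tightBefore=logical, meta=...)
        pos <- 0L
        seqParts <- character(0)
        entries <- list()
        for (it in items) {
          gap <- if (isTRUE(it$tight)) sample(100:700, 1L)
                 else sample(300:2000, 1L)
          seqParts <- c(seqParts, .randDna(gap))
          pos <- pos + gap
          geneCounter <<- geneCounter + 1L
          id <- sprintf("%s_g%03d", asm, geneCounter)
          gene <- it$gene
          fragLen <- nchar(gene$frag)
          entry <- list(id = id, contig = ctgName, start = pos + 1L,
                        end = pos + fragLen, strand = gene$strand,
                        product = gene$product, protein = gene$protein,
                        role = gene$role, plantRow = it$plantRow %||% NA,
                        exons = lapply(gene$exonsLocal, function(e)
                          e + pos))
          seqParts <- c(seqParts, gene$frag)
          pos <- pos + fragLen
          entries <- c(entries, list(entry))
        }
        seqParts <- c(seqParts, .randDna(sample(300:800, 1L)))
        list(seq = paste(seqParts, collapse = ""), entries = entries)
      }

      items <- list()
      bi <- 0L
      addBg <- function(upTo) {
        while (bi < upTo) {
          bi <<- bi + 1L
          items[[length(items) + 1L]] <<- list(gene = bg[[bi]],
                                               tight = FALSE)
        }
      }
      for (k in seq_len(K)) {
        addBg(ins[k])
        blk <- blocks[[g]][[k]]
        half <- length(blk$flanks) %/% 2L
        seqGenes <- c(if (length(blk$flanks)) blk$flanks[seq_len(half)],
                      blk$cluster,
                      if (length(blk$flanks) > half)
                        blk$flanks[(half + 1L):length(blk$flanks)])
        first <- TRUE
        for (gene in seqGenes) {
          items[[length(items) + 1L]] <- list(gene = gene, tight = !first,
                                              plantRow = blk$plantRow)
          first <- FALSE
        }
      }
      addBg(nB)
      c1 <- layoutContig(items, "ctg1")
      ctgSeqs <- setNames(list(c1$seq), sprintf("%s_ctg1", asm))
      entries <- lapply(c1$entries, function(e) {
        e$contig <- sprintf("%s_ctg1", asm); e
      })
      if (length(contig2[[g]])) {
        items2 <- lapply(contig2[[g]], function(gene)
          list(gene = gene, tight = FALSE))
        c2 <- layoutContig(items2, "ctg2")
        ctgSeqs[[sprintf("%s_ctg2", asm)]] <- c2$seq
        entries <- c(entries, lapply(c2$entries, function(e) {
          e$contig <- sprintf("%s_ctg2", asm); e
        }))
      }

      # truth per plant in this genome
      plantTruth <- list()
      for (k in seq_len(K)) {
        pr <- blocks[[g]][[k]]$plantRow
        p <- plants[pr, ]
        pe <- Filter(function(e) identical(e$plantRow, pr), entries)
        roles <- vapply(pe, function(e) e$role, "")
        clusterGenes <- pe[roles %in% c("core", "hook", "accessory")]
        plantTruth[[length(plantTruth) + 1L]] <- list(
          plantId = sprintf("%s_p%02d", asm, k),
          kind = p$kind, familyLabel = p$familyLabel,
          hookId = p$hookId, identityToHook = p$identityToHook,
          outsideCopies = p$outsideCopies,
          contig = clusterGenes[[1L]]$contig,
          start = min(vapply(clusterGenes, function(e) e$start, 0L)),
          end = max(vapply(clusterGenes, function(e) e$end, 0L)),
          geneIds = vapply(clusterGenes, function(e) e$id, ""),
          coreGene = vapply(pe[roles == "core"], function(e) e$id, ""),
          hookGene = if (any(roles == "hook"))
            vapply(pe[roles == "hook"], function(e) e$id, "") else character(0),
          flankGenes = vapply(pe[roles == "flank"], function(e) e$id, ""),
          expectedFlag = identical(p$kind, "true_resistant_bgc"))
      }
      outsideIds <- vapply(Filter(function(e) e$role == "outside_copy",
                                  entries), function(e) e$id, "")

      fastaPaths[g] <- file.path(outDir, sprintf("%s.fna", asm))
      .writeFasta(ctgSeqs, fastaPaths[g])
      gffPaths[g] <- file.path(outDir, sprintf("%s.gff3", asm))
      .writeGff3(entries, lapply(ctgSeqs, nchar), gffPaths[g])
      taxaRows[[g]] <- data.frame(
        assembly_id = asm,
        organism = sprintf("%s sp. %s", config$taxa$genus[g], asm),
        genus = config$taxa$genus[g], class = config$taxa$class[g],
        stringsAsFactors = FALSE)
      truthGenomes[[asm]] <- list(
        assemblyId = asm, plants = plantTruth,
        outsideCopyGenes = outsideIds,
        genes = lapply(entries, function(e)
          list(id = e$id, role = e$role, protein = e$protein)))
    }

    taxonTsv <- file.path(outDir, "taxa.tsv")
    .writeTsv(do.call(rbind, taxaRows), taxonTsv)
    truth <- list(runId = sprintf("sim_seed%d_n%d", config$seed, nG),
                  seed = config$seed, assemblies = asmIds,
                  genomes = truthGenomes)
    truthJson <- file.path(outDir, "truth.json")
    jsonlite::write_json(truth, truthJson, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    if (audit) .auditSim(fastaPaths, gffPaths, taxonTsv, truth)
    invisible(list(fasta = fastaPaths, gff = gffPaths,
                   taxonTsv = taxonTsv, truthJson = truthJson,
                   truth = truth))
  })
}

# self-audit: re-read emitted files; every recorded gene must come back
# with exactly the planted protein
.auditSim <- function(fastaPaths, gffPaths, taxonTsv, truth) {
  taxa <- readTaxonTable(taxonTsv)
  for (g in seq_along(fastaPaths)) {
    gn <- readGenome(fastaPaths[g], gffPaths[g], taxa[g, ])
    prot <- extractProteome(gn)
    rec <- truth$genomes[[assemblyId(gn)]]
    for (ge in rec$genes) {
      got <- as.character(prot[[ge$id]])
      if (!identical(got, ge$protein))
        stop("self-audit failed: gene ", ge$id,
             " does not reproduce its planted protein")
    }
  }
  invisible(TRUE)
}

#' Load a truth JSON written by [generateGenomes()]
#' @param path truth.json path
#' @return the `SimTruth` list
#' @export
readSimTruth <- function(path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)

# --- recovery scoring -----------------------------------------------------

#' Score pipeline output against planted truth
#'
#' Compares the flagged regions and families of a run against the ground
#' truth of the synthetic genomes the run consumed. A truth plant is
#' recovered when a flagged region on the same assembly and contig overlaps
#' its interval.
#'
#' * `flagRecall`: recovered truth positives / truth positives
#' * `flagPrecision`: flagged regions matching a truth positive / flagged
#'   regions (reported as 1 with a notice when nothing is flagged)
#' * `boundaryExactness`: fraction of recovered positives whose final
#'   region gene set equals the planted cluster gene set exactly
#' * `familyPairAgreement`: fraction of same-family truth-positive pairs
#'   whose regions end up in the same refined family
#'
#' @param output a `RunReport` from [runMine()], or a list with elements
#'   `flaggedRegions` (list of [BGCRegion-class]) and `familiesRefined`
#'   (list of [Family-class])
#' @param truth the `SimTruth` from [generateGenomes()] /
#'   [readSimTruth()] for the same run
#' @return list with the four scores, the underlying counts, and notices
#' @export
evaluateRecovery <- function(output, truth) {
  regions <- output$flaggedRegions
  families <- output$familiesRefined %||% output$families %||% list()
  outAsm <- sort(unique(vapply(regions, assemblyId, "")))
  truthAsm <- sort(unlist(truth$assemblies))
  if (length(outAsm) && !all(outAsm %in% truthAsm))
    stop("mismatched runs: output assemblies not in truth (",
         paste(setdiff(outAsm, truthAsm), collapse = ", "), ")")

  plantsAll <- list()
  for (gn in truth$genomes)
    for (p in gn$plants) {
      p$assemblyId <- gn$assemblyId
      plantsAll[[p$plantId]] <- p
    }
  positives <- Filter(function(p) isTRUE(p$expectedFlag), plantsAll)

  matchOf <- function(p) {
    for (r in regions) {
      if (r@assemblyId != p$assemblyId || r@contigId != p$contig) next
      if (IRanges::start(r@range) <= p$end && IRanges::end(r@range) >= p$start)
        return(r)
    }
    NULL
  }
  matched <- lapply(positives, matchOf)
  nRecovered <- sum(!vapply(matched, is.null, TRUE))
  recall <- if (length(positives)) nRecovered / length(positives) else 1

  notices <- character(0)
  if (!length(regions)) {
    precision <- 1
    notices <- c(notices, "no regions flagged; precision reported as 1")
  } else {
    isTP <- vapply(regions, function(r) {
      any(vapply(positives, function(p)
        r@assemblyId == p$assemblyId && r@contigId == p$contig &&
          IRanges::start(r@range) <= p$end &&
          IRanges::end(r@range) >= p$start, TRUE))
    }, TRUE)
    precision <- sum(isTP) / length(regions)
  }

  exact <- vapply(seq_along(positives), function(i) {
    r <- matched[[i]]
    if (is.null(r)) return(NA)
    setequal(geneIds(r), unlist(positives[[i]]$geneIds))
  }, TRUE)
  boundary <- if (nRecovered) mean(exact, na.rm = TRUE) else 0

  # same-family truth pairs co-clustered
  famOf <- setNames(rep(NA_character_, length(positives)), names(positives))
  for (f in families) {
    rid <- vapply(f@members, regionId, "")
    for (i in seq_along(positives)) {
      r <- matched[[i]]
      if (!is.null(r) && r@regionId %in% rid)
        famOf[i] <- f@familyId
    }
  }
  labels <- vapply(positives, function(p) p$familyLabel, "")
  pairsTotal <- 0L; pairsOk <- 0L
  if (length(positives) > 1L) {
    for (i in seq_len(length(positives) - 1L))
      for (j in seq.int(i + 1L, length(positives)))
        if (labels[i] == labels[j]) {
          pairsTotal <- pairsTotal + 1L
          if (!is.na(famOf[i]) && !is.na(famOf[j]) && famOf[i] == famOf[j])
            pairsOk <- pairsOk + 1L
        }
  }
  agreement <- if (pairsTotal) pairsOk / pairsTotal else {
    notices <- c(notices, "no same-family truth pairs; agreement reported as 1")
    1
  }

  list(flagRecall = recall, flagPrecision = precision,
       boundaryExactness = boundary, familyPairAgreement = agreement,
       counts = list(truthPositives = length(positives),
                     recovered = nRecovered, flagged = length(regions),
                     sameFamilyPairs = pairsTotal),
       notices = notices)
}
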