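#' Pairwise BGC similarity components
#'
#' @slot jaccard shared gene-content index in [0,1]
#' @slot adjacency shared unordered adjacent-pair index in [0,1]
#' @slot identity mean best-match percent identity of matched genes, scaled
#'   to [0,1]
#' @slot combined weighted sum of the three components
#' @slot weights the weights used (sum to 1)
#' @exportClass BGCPairSimilarity
setClass("BGCPairSimilarity",
  representation(jaccard = "numeric", adjacency = "numeric",
                 identity = "numeric", combined = "numeric",
                 weights = "numeric"),
  validity = function(object) {
    v <- c(object@jaccard, object@adjacency, object@identity,
           object@combined)
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      return("all similarity components must lie in [0,1]")
    if (abs(sum(object@weights) - 1) > 1e-9)
      return("weights must sum to 1")
    TRUE
  })

setMethod("show", "BGCPairSimilarity", function(object) {
  cat(sprintf(
    "BGCPairSimilarity: jaccard=%.3f adjacency=%.3f identity=%.3f -> combined=%.3f\n",
    object@jaccard, object@adjacency, object@identity, object@combined))
})

# reciprocal-best-hit matching of genes between two regions; mutual
# coverage keeps short spurious local matches between unrelated proteins
# from counting as shared genes
.matchRegionGenes <- function(r1, r2, minIdentity, minCoverage, scheme) {
  p1 <- setNames(S4Vectors::mcols(genes(r1))$protein, geneIds(r1))
  p2 <- setNames(S4Vectors::mcols(genes(r2))$protein, geneIds(r2))
  tb <- alignPairs(p1, p2, scheme = scheme)
  tb <- tb[tb$percentIdentity >= minIdentity &
           tb$queryCoverage >= minCoverage &
           tb$targetCoverage >= minCoverage, , drop = FALSE]
  if (!nrow(tb))
    return(data.frame(g1 = character(), g2 = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  tb <- tb[order(tb$queryId, -tb$score, tb$targetId), , drop = FALSE]
  fwd <- tb[!duplicated(tb$queryId), , drop = FALSE]
  tb2 <- tb[order(tb$targetId, -tb$score, tb$queryId), , drop = FALSE]
  rev <- tb2[!duplicated(tb2$targetId), , drop = FALSE]
  key <- paste(fwd$queryId, fwd$targetId)
  keep <- key %in% paste(rev$queryId, rev$targetId)
  data.frame(g1 = fwd$queryId[keep], g2 = fwd$targetId[keep],
             identity = fwd$percentIdentity[keep], stringsAsFactors = FALSE)
}

#' Similarity between two BGC regions
#'
#' Genes are matched across the two regions by reciprocal best local
#' alignment at `>= minIdentity` percent identity. Three components are
#' combined: the Jaccard index of matched gene content (unmatched genes
#' count in the denominator only), an adjacency index (Jaccard of the sets
#' of unordered adjacent matched-gene pairs, so gene-order reversal is
#' neutral), and the mean identity of matched pairs scaled to [0,1]
#' (0 when nothing matches). `combined` is the weighted sum.
#'
#' @param r1,r2 [BGCRegion-class] objects
#' @param weights numeric length 3 summing to 1: Jaccard, adjacency,
#'   identity (default `c(0.3, 0.2, 0.5)`)
#' @param minIdentity gene-matching identity threshold (default 40)
#' @param minCoverage gene-matching mutual coverage threshold, applied to
#'   both genes of a pair (default 0.6)
#' @param scheme a [ScoringScheme-class]
#' @return a [BGCPairSimilarity-class]
#' @export
bgcSimilarity <- function(r1, r2, weights = c(0.3, 0.2, 0.5),
                          minIdentity = 40, minCoverage = 0.6,
                          scheme = scoringScheme()) {
  stopifnot(is(r1, "BGCRegion"), is(r2, "BGCRegion"),
            length(weights) == 3L, abs(sum(weights) - 1) < 1e-9)
  mm <- .matchRegionGenes(r1, r2, minIdentity, minCoverage, scheme)
  n1 <- nGenes(r1); n2 <- nGenes(r2); m <- nrow(mm)
  jac <- if (n1 + n2 - m > 0L) m / (n1 + n2 - m) else 0

  ident <- if (m) mean(mm$identity) / 100 else 0

  # unordered adjacent pairs, expressed in r2 gene ids
  partner <- setNames(mm$g2, mm$g1)
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  adjPairs <- function(ids, mapTo = NULL) {
    if (length(ids) < 2L) return(character())
    a <- ids[-length(ids)]; b <- ids[-1L]
    if (!is.null(mapTo)) { a <- mapTo[a]; b <- mapTo[b] }
    ok <- !is.na(a) & !is.na(b)
    unique(pairKey(a[ok], b[ok]))
  }
  P1 <- adjPairs(geneIds(r1), partner)
  matched2 <- geneIds(r2)
  matched2[!matched2 %in% mm$g2] <- NA
  P2 <- adjPairs(matched2, NULL)
  # with no adjacent pairs on either side the index is defined as 1 only
  # when the regions are single genes matching each other completely
  # (self-comparison of a one-gene region); a lone shared gene between
  # larger regions carries no adjacency signal
  adj <- if (length(P1) || length(P2))
    length(intersect(P1, P2)) / length(union(P1, P2))
  else if (m >= 1L && m == n1 && m == n2) 1 else 0

  comb <- weights[1L] * jac + weights[2L] * adj + weights[3L] * ident
  new("BGCPairSimilarity", jaccard = jac, adjacency = adj,
      identity = ident, combined = comb, weights = weights)
}

# region-level summaries used for family signatures
.memberCoreMultiset <- function(r)
  sort(vapply(r@cores, function(co) co@coreClass, ""))

.memberBestHook <- function(r) {
  if (!length(r@hookHits)) return("")
  sc <- vapply(r@hookHits, function(h) h$hit@score, 0L)
  r@hookHits[[order(-sc, names(r@hookHits))[1L]]]$hookId
}

.makeFamily <- function(id, memberList) {
  cls <- vapply(memberList, function(r) r@taxonomicClass, "")
  tb <- table(cls)
  multis <- lapply(memberList, .memberCoreMultiset)
  hooks <- vapply(memberList, .memberBestHook, "")
  homogeneous <- length(unique(vapply(multis, paste, "", collapse = "+"))) == 1L
  new("Family", familyId = id, members = memberList,
      coreSignature = if (homogeneous) multis[[1L]]
                      else sort(unique(unlist(multis))),
      hookSignature = if (length(unique(hooks)) == 1L) hooks[1L] else "",
      genera = sort(unique(vapply(memberList, function(r) r@genus, ""))),
      classCounts = setNames(as.integer(tb), names(tb)))
}

# deterministic family ids: rank by smallest member region id
.assignFamilyIds <- function(memberLists) {
  if (!length(memberLists)) return(list())
  minId <- vapply(memberLists,
                  function(ms) min(vapply(ms, regionId, "")), "")
  memberLists <- memberLists[order(minId)]
  lapply(seq_along(memberLists), function(i)
    .makeFamily(sprintf("F%03d", i), memberLists[[i]]))
}

#' Group regions into gene-cluster families
#'
#' Single-linkage clustering: regions are connected when their pairwise
#' distance `1 - combined` is at most `cutoff`, and connected components
#' become families. Family ids are deterministic (ordered by the smallest
#' member region id) and independent of input order.
#'
#' @param regions list of [BGCRegion-class] (typically the flagged ones)
#' @param cutoff maximum joining distance (default 0.3)
#' @inheritParams bgcSimilarity
#' @return list of [Family-class]
#' @seealso [refineFamilies()], [dropSingleGenus()]
#' @export
clusterFamilies <- function(regions, cutoff = 0.3,
                            weights = c(0.3, 0.2, 0.5), minIdentity = 40,
                            minCoverage = 0.6, scheme = scoringScheme()) {
  if (!length(regions)) return(list())
  ids <- vapply(regions, regionId, "")
  if (anyDuplicated(ids)) stop("duplicate region ids")
  regions <- regions[order(ids)]
  ids <- sort(ids)
  n <- length(regions)
  edges <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- bgcSimilarity(regions[[i]], regions[[j]], weights = weights,
                           minIdentity = minIdentity,
                           minCoverage = minCoverage, scheme = scheme)
        if (1 - s@combined <= cutoff) edges <- c(edges, i, j)
      }
    }
  }
  gr <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(gr)$membership
  memberLists <- lapply(split(seq_len(n), comp), function(ix) regions[ix])
  .assignFamilyIds(unname(memberLists))
}

#' Refine families to a shared core and hook signature
#'
#' Partitions every family by the key (core-class multiset, best hook id)
#' so that each refined family comprises only BGCs sharing the same core
#' enzymes and the same housekeeping hook. Never merges families;
#' idempotent. Ids are re-derived deterministically.
#'
#' @param families list of [Family-class]
#' @return list of [Family-class]
#' @export
refineFamilies <- function(families) {
  memberLists <- list()
  for (fam in families) {
    keys <- vapply(fam@members, function(r)
      paste(paste(.memberCoreMultiset(r), collapse = "+"),
            .memberBestHook(r), sep = "|"), "")
    memberLists <- c(memberLists,
                     unname(lapply(split(fam@members, keys), identity)))
  }
  .assignFamilyIds(memberLists)
}

#' Drop single-genus families
#'
#' Families whose members all come from one genus are excluded as likely
#' false positives (vertical inheritance rather than a shared, horizontally
#' maintained cluster); only families spanning >= 2 genera are kept.
#'
#' @param families list of [Family-class]
#' @return filtered list of [Family-class]
#' @export
dropSingleGenus <- function(families) {
  Filter(function(f) length(f@genera) >= 2L, families)
}

#' Summarize families by taxonomic class
#'
#' @param families list of [Family-class]
#' @return list with `byFamily` (data.frame, one row per family, one column
#'   per taxonomic class, deterministic order) and `classTotals` (named
#'   integer). Counts sum to the total number of member regions.
#' @export
taxonomySummary <- function(families) {
  if (!length(families)) {
    return(list(byFamily = data.frame(family_id = character()),
                classTotals = setNames(integer(0), character(0))))
  }
  classes <- sort(unique(unlist(lapply(families,
                                       function(f) names(f@classCounts)))))
  ids <- vapply(families, familyId, "")
  mat <- matrix(0L, nrow = length(families), ncol = length(classes),
                dimnames = list(ids, classes))
  for (i in seq_along(families)) {
    cc <- families[[i]]@classCounts
    mat[i, names(cc)] <- cc
  }
  ord <- order(ids)
  mat <- mat[ord, , drop = FALSE]
  df <- data.frame(family_id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  list(byFamily = df, classTotals = colSums(mat))
}

#' Tabulate families
#'
#' @param families list of [Family-class]
#' @return data.frame with columns family_id, n_members, core_signature,
#'   hook_id, genera, classes
#' @export
familyTable <- function(families) {
  rows <- lapply(families, function(f) data.frame(
    family_id = f@familyId, n_members = length(f@members),
    core_signature = paste(f@coreSignature, collapse = "+"),
    hook_id = f@hookSignature,
    genera = paste(f@genera, collapse = ","),
    classes = paste(sprintf("%s:%d", names(f@classCounts), f@classCounts),
                    collapse = ","),
    stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame()
}

#' Import an externally computed family assignment
#'
#' Adapter for parity runs against an external clustering tool: a TSV with
#' columns `region_id` and `family` assigns each region to a family label;
#' regions sharing a label become one family (ids re-derived
#' deterministically).
#'
#' @param regions list of [BGCRegion-class]
#' @param path assignment TSV
#' @return list of [Family-class]
#' @export
importFamilyAssignments <- function(regions, path) {
  df <- .readTsv(path)
  if (!all(c("region_id", "family") %in% colnames(df)))
    stop("assignment TSV needs columns region_id, family")
  ids <- vapply(regions, regionId, "")
  mi <- match(ids, df$region_id)
  if (anyNA(mi))
    stop("assignment missing for region(s): ",
         paste(ids[is.na(mi)], collapse = ", "))
  .assignFamilyIds(unname(lapply(split(regions, df$family[mi]), identity)))
}
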