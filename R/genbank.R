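# Minimal GenBank flat-file support: enough for annotated fungal loci and
# for round-tripping extracted BGC regions (CDS features with locus_tag,
# product, translation; join()/complement() compound locations).

# --- location parsing -----------------------------------------------------

# returns list(strand, ranges = IRanges) or NULL when unparsable
.parseLocation <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join|order", loc)) return(NULL)  # nested forms
  parts <- strsplit(loc, ",")[[1L]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  st <- en <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (length(m[[i]]) == 3L) {
      st[i] <- as.integer(m[[i]][2L]); en[i] <- as.integer(m[[i]][3L])
    } else if (length(single[[i]]) == 2L) {
      st[i] <- en[i] <- as.integer(single[[i]][2L])
    } else return(NULL)
  }
  list(strand = strand, ranges = IRanges::IRanges(st, en))
}

.formatLocation <- function(ranges, strand) {
  seg <- sprintf("%d..%d", IRanges::start(ranges), IRanges::end(ranges))
  loc <- if (length(seg) > 1L) paste0("join(", paste(seg, collapse = ","), ")")
         else seg
  if (strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

# --- reader ---------------------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Parses one or more GenBank records (each becomes a contig) with their CDS
#' features. A stored `/translation` is preferred over re-translation; a CDS
#' lacking a translation is spliced and translated from the record sequence.
#' A CDS lacking both a translation and a parsable location is skipped with
#' a warning. `join(...)` and `complement(...)` compound locations are
#' supported.
#'
#' @param path GenBank flat file (possibly multi-record)
#' @inheritParams readGenome
#' @return a [GenomeRecord-class]
#' @seealso [readGenome()], [writeBgcGenBank()]
#' @export
readGenBank <- function(path, taxonMetadata) {
  taxon <- .taxonRow(taxonMetadata)
  lines <- readLines(path)
  recEnd <- grep("^//\\s*$", lines)
  recStart <- c(1L, utils::head(recEnd, -1L) + 1L)
  if (!length(recEnd)) stop("no GenBank record terminator '//' found")

  contigSeqs <- character(); contigNames <- character()
  tab <- list(geneID = character(), contig = character(), start = integer(),
              end = integer(), strand = character(), protein = character(),
              product = character(), exons = IRanges::IRangesList())
  autoId <- 0L

  for (r in seq_along(recEnd)) {
    rec <- lines[recStart[r]:recEnd[r]]
    locusLine <- grep("^LOCUS", rec, value = TRUE)
    if (!length(locusLine)) stop("record without LOCUS line")
    ctg <- strsplit(trimws(sub("^LOCUS", "", locusLine[1L])), "\\s+")[[1L]][1L]

    # sequence
    oi <- grep("^ORIGIN", rec)
    seqTxt <- ""
    if (length(oi)) {
      body <- rec[(oi[1L] + 1L):length(rec)]
      body <- body[!grepl("^//", body)]
      seqTxt <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    contigNames <- c(contigNames, ctg)
    contigSeqs <- c(contigSeqs, seqTxt)

    # feature table
    fi <- grep("^FEATURES", rec)
    if (!length(fi)) next
    fend <- if (length(oi)) oi[1L] - 1L else length(rec)
    ft <- rec[(fi[1L] + 1L):fend]
    # a new feature starts at column 6; qualifier/continuation lines at 22
    isKey <- grepl("^ {5}\\S", ft)
    keyIdx <- which(isKey)
    for (k in seq_along(keyIdx)) {
      from <- keyIdx[k]
      to <- if (k < length(keyIdx)) keyIdx[k + 1L] - 1L else length(ft)
      key <- strsplit(trimws(ft[from]), "\\s+")[[1L]][1L]
      if (key != "CDS") next
      block <- ft[from:to]
      # location possibly continued before first qualifier
      qstart <- grep("^\\s+/", block)[1L]
      locEnd <- if (is.na(qstart)) length(block) else qstart - 1L
      loc <- paste(trimws(sub("^\\s*CDS", "", block[1:locEnd])),
                   collapse = "")
      quals <- if (is.na(qstart)) character() else block[qstart:length(block)]
      getQual <- function(name) {
        hit <- grep(paste0("^\\s+/", name, "="), quals)
        if (!length(hit)) return(NULL)
        val <- sub(paste0("^\\s+/", name, "="), "", quals[hit[1L]])
        nxt <- hit[1L] + 1L
        while (nxt <= length(quals) && !grepl("^\\s+/", quals[nxt])) {
          val <- paste0(val, trimws(quals[nxt]))
          nxt <- nxt + 1L
        }
        gsub("\"", "", val)
      }
      parsed <- .parseLocation(loc)
      translation <- getQual("translation")
      if (is.null(parsed) && is.null(translation)) {
        warning(sprintf("CDS with unparsable location '%s' skipped", loc),
                call. = FALSE)
        next
      }
      if (is.null(parsed))
        stop(sprintf("CDS with translation but unparsable location '%s'",
                     loc))
      aa <- translation
      if (is.null(aa)) {
        if (!nzchar(seqTxt)) {
          warning("CDS without translation in a sequence-less record; skipped",
                  call. = FALSE)
          next
        }
        aa <- .spliceTranslate(Biostrings::DNAString(seqTxt), parsed$ranges,
                               parsed$strand, 0L)
        if (is.null(aa)) {
          warning(sprintf("CDS at '%s': length not divisible by 3; skipped",
                          loc), call. = FALSE)
          next
        }
      }
      autoId <- autoId + 1L
      gid <- getQual("locus_tag") %||% getQual("gene") %||%
        sprintf("%s_cds%03d", ctg, autoId)
      tab$geneID <- c(tab$geneID, gid)
      tab$contig <- c(tab$contig, ctg)
      tab$start <- c(tab$start, min(IRanges::start(parsed$ranges)))
      tab$end <- c(tab$end, max(IRanges::end(parsed$ranges)))
      tab$strand <- c(tab$strand, parsed$strand)
      tab$protein <- c(tab$protein, aa)
      tab$product <- c(tab$product, getQual("product") %||% "")
      tab$exons <- c(tab$exons, IRanges::IRangesList(parsed$ranges))
    }
  }

  contigs <- Biostrings::DNAStringSet(setNames(contigSeqs, contigNames))
  # records without ORIGIN: give the contig the minimal length covering its
  # features so interval validity holds
  w <- Biostrings::width(contigs)
  for (i in which(w == 0L)) {
    onCtg <- tab$contig == contigNames[i]
    len <- if (any(onCtg)) max(tab$end[onCtg]) else 1L
    contigs[[i]] <- Biostrings::DNAString(paste(rep("N", len), collapse = ""))
  }
  .newGenome(taxon, contigs, tab)
}

# --- writer ---------------------------------------------------------------

#' Export a BGC region as a GenBank record
#'
#' Writes the region as a single GenBank record with local (re-based)
#' coordinates: a gene at genomic position p appears at p - regionStart + 1.
#' Every member gene is emitted as a CDS with `/locus_tag`, `/product` and
#' `/translation`; core genes carry `/core_class` and hook-hit genes carry
#' `/hook_id` plus `/hook_identity` qualifiers.
#'
#' @param genome the [GenomeRecord-class] the region came from
#' @param region a [BGCRegion-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeBgcGenBank <- function(genome, region, path) {
  stopifnot(is(genome, "GenomeRecord"), is(region, "BGCRegion"))
  ctg <- region@contigId
  if (!ctg %in% names(contigs(genome)))
    stop(sprintf("region contig '%s' not in genome", ctg))
  rs <- IRanges::start(region@range); re <- IRanges::end(region@range)
  clen <- Biostrings::width(contigs(genome))[match(ctg, names(contigs(genome)))]
  if (rs < 1L || re > clen)
    stop(sprintf("region %d-%d outside contig '%s' (length %d)",
                 rs, re, ctg, clen))
  seqTxt <- as.character(Biostrings::subseq(contigs(genome)[[ctg]], rs, re))
  len <- nchar(seqTxt)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   PLN",
                     region@regionId, len), con)
  writeLines(sprintf("DEFINITION  candidate BGC region %s from %s (%s).",
                     region@regionId, assemblyId(genome),
                     organismName(genome)), con)
  writeLines(sprintf("ACCESSION   %s", region@regionId), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  writeLines(sprintf("                     /organism=\"%s\"",
                     organismName(genome)), con)

  wq <- function(name, value) {
    txt <- sprintf("/%s=\"%s\"", name, value)
    # fold long qualifiers at 58 chars of content
    while (nchar(txt) > 58L) {
      writeLines(paste0(strrep(" ", 21L), substr(txt, 1L, 58L)), con)
      txt <- substr(txt, 59L, nchar(txt))
    }
    writeLines(paste0(strrep(" ", 21L), txt), con)
  }

  g <- genes(region)
  mc <- S4Vectors::mcols(g)
  for (i in seq_along(g)) {
    exons <- mc$exons[[i]]
    local <- IRanges::shift(exons, -(rs - 1L))
    strand <- as.character(GenomicRanges::strand(g))[i]
    writeLines(sprintf("     CDS             %s",
                       .formatLocation(local, strand)), con)
    wq("locus_tag", mc$geneID[i])
    if (nzchar(mc$product[i])) wq("product", mc$product[i])
    co <- region@cores[[mc$geneID[i]]]
    if (!is.null(co)) wq("core_class", co@coreClass)
    hh <- region@hookHits[[mc$geneID[i]]]
    if (!is.null(hh)) {
      wq("hook_id", hh$hookId)
      wq("hook_identity", sprintf("%.1f", hh$hit@percentIdentity))
    }
    wq("translation", mc$protein[i])
  }

  writeLines("ORIGIN", con)
  lower <- tolower(seqTxt)
  pos <- seq.int(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substr(lower, p, min(p + 59L, len))
    tens <- .wrapSeq(chunk, 10L)
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
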