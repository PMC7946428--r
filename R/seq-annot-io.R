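## Locus / annotation input and sequence output.
##
## Genome FASTA is read with Biostrings, annotation GFF3 with rtracklayer.
## Minus-strand genes are normalised to the sense strand immediately after
## load, so every downstream module works on a plus-strand gene model.

#' AnnotatedRecord: a sequence plus a flat feature table
#'
#' @slot name record identifier.
#' @slot seq DNA sequence.
#' @slot features data.frame with columns label, start, end, strand and
#'   optionally note; 1-based closed intervals within the sequence.
#' @export
setClass("AnnotatedRecord", representation(
  name = "character", seq = "character", features = "data.frame"
))

setValidity("AnnotatedRecord", function(object) {
  f <- object@features
  if (nrow(f) &&
      (any(f$start < 1L) || any(f$end > nchar(object@seq)) ||
       any(f$end < f$start)))
    return("feature interval outside sequence bounds")
  TRUE
})

#' Construct an AnnotatedRecord
#' @param name,seq,features see class slots.
#' @return an \code{AnnotatedRecord}.
#' @export
AnnotatedRecord <- function(name, seq, features = data.frame()) {
  if (nrow(features) && is.null(features$strand)) features$strand <- "+"
  new("AnnotatedRecord", name = name, seq = assertDNA(seq),
      features = as.data.frame(features))
}

setMethod("show", "AnnotatedRecord", function(object) {
  cat("AnnotatedRecord:", object@name, "|", nchar(object@seq), "bp |",
      nrow(object@features), "feature(s)\n")
})

#' Load a gene locus from FASTA + GFF3
#'
#' Extracts the gene span plus \code{flank} bp on each side from the genome,
#' rebases all annotation to the extracted sequence, and normalises
#' minus-strand genes to the sense strand (sequence reverse-complemented,
#' exon order 5' to 3'). When a gene has several mRNAs the transcript with
#' the longest CDS is used.
#'
#' @param genomePath FASTA file with the chromosome/contig sequences.
#' @param gffPath GFF3 file with gene/mRNA/exon/CDS (and optionally UTR)
#'   features; \code{ID}/\code{Parent} attributes link the hierarchy.
#' @param geneId the gene to extract (matched against ID, Name, gene_id).
#' @param flank bp of context kept on each side of the gene span.
#' @return list with elements \code{locus} (named DNA string) and
#'   \code{model} (a \code{\link{GeneModel}} in locus coordinates).
#' @export
loadLocus <- function(genomePath, gffPath, geneId, flank = 0L) {
  stopifnot(flank >= 0L)
  genome <- Biostrings::readDNAStringSet(genomePath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gffPath, format = "gff3")

  ids <- as.character(S4Vectors::mcols(gff)$ID %||% rep(NA, length(gff)))
  nms <- as.character(S4Vectors::mcols(gff)$Name %||% rep(NA, length(gff)))
  isGene <- S4Vectors::mcols(gff)$type == "gene"
  hit <- which(isGene & (ids == geneId | nms == geneId))
  if (!length(hit)) stop("gene not found: ", geneId)
  gene <- gff[hit[1L]]
  gid <- ids[hit[1L]]

  parentOf <- function(x) {
    p <- S4Vectors::mcols(x)$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v)[1] else NA_character_,
           character(1))
  }
  mrna <- gff[S4Vectors::mcols(gff)$type %in% c("mRNA", "transcript") &
              parentOf(gff) == gid]
  exonFeat <- gff[S4Vectors::mcols(gff)$type == "exon"]
  cdsFeat <- gff[S4Vectors::mcols(gff)$type == "CDS"]
  if (length(mrna)) {
    mids <- as.character(S4Vectors::mcols(mrna)$ID)
    cdsLen <- vapply(mids, function(m)
      sum(GenomicRanges::width(cdsFeat[parentOf(cdsFeat) == m])), numeric(1))
    tx <- mids[which.max(cdsLen)]
    exonFeat <- exonFeat[parentOf(exonFeat) == tx]
    cdsFeat <- cdsFeat[parentOf(cdsFeat) == tx]
  } else {
    exonFeat <- exonFeat[parentOf(exonFeat) == gid]
    cdsFeat <- cdsFeat[parentOf(cdsFeat) == gid]
  }
  if (!length(exonFeat) || !length(cdsFeat))
    stop("annotation inconsistent: gene ", geneId, " lacks exon or CDS features")

  chrom <- as.character(GenomicRanges::seqnames(gene))[1]
  if (!chrom %in% names(genome))
    stop("annotation inconsistent: sequence ", chrom, " not in genome FASTA")
  chromSeq <- genome[[chrom]]
  gStart <- max(1L, GenomicRanges::start(gene) - as.integer(flank))
  gEnd <- min(length(chromSeq), GenomicRanges::end(gene) + as.integer(flank))
  if (min(GenomicRanges::start(exonFeat)) < GenomicRanges::start(gene) ||
      max(GenomicRanges::end(exonFeat)) > GenomicRanges::end(gene))
    stop("annotation inconsistent: exons outside the gene span")

  locusSeq <- as.character(Biostrings::subseq(chromSeq, gStart, gEnd))
  locusSeq <- assertDNA(locusSeq, "locus")
  strand <- as.character(GenomicRanges::strand(gene))[1]
  width <- gEnd - gStart + 1L

  ex <- IRanges::IRanges(GenomicRanges::start(exonFeat) - gStart + 1L,
                         GenomicRanges::end(exonFeat) - gStart + 1L)
  cdsS <- min(GenomicRanges::start(cdsFeat)) - gStart + 1L
  cdsE <- max(GenomicRanges::end(cdsFeat)) - gStart + 1L
  if (strand == "-") {
    locusSeq <- revComp(locusSeq)
    flip <- function(s, e) IRanges::IRanges(width - e + 1L, width - s + 1L)
    ex <- flip(IRanges::start(ex), IRanges::end(ex))
    tmp <- cdsS
    cdsS <- width - cdsE + 1L
    cdsE <- width - tmp + 1L
  }
  ex <- ex[order(IRanges::start(ex))]
  model <- GeneModel(geneId = geneId, chrom = chrom, strand = strand,
                     exons = ex, cdsStart = cdsS, cdsEnd = cdsE,
                     origin = list(start = gStart, end = gEnd, width = width))
  locus <- setNames(locusSeq, paste0(geneId, "_locus"))
  list(locus = locus, model = model)
}

#' Map sense-locus coordinates back to native genome coordinates
#'
#' Inverse of the rebasing performed by \code{\link{loadLocus}}; used to
#' verify the coordinate round-trip against the source GFF3.
#'
#' @param model a GeneModel produced by loadLocus.
#' @param ranges IRanges in locus (sense) coordinates.
#' @return IRanges in native genome coordinates.
#' @export
locusToGenome <- function(model, ranges) {
  o <- model@origin
  if (model@strand == "+") {
    IRanges::shift(ranges, o$start - 1L)
  } else {
    IRanges::IRanges(o$start + o$width - IRanges::end(ranges),
                     o$start + o$width - IRanges::start(ranges))
  }
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, assertDNA, character(1)))
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file to a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## GenBank flat-file output: no installed package writes GenBank, so a
## minimal LOCUS/FEATURES/ORIGIN dialect is emitted (and re-read for
## round-trip checks).

#' Write an AnnotatedRecord as a GenBank flat file
#'
#' Emits a minimal single-record GenBank file: LOCUS line, one
#' misc_feature per feature row (with /label and optional /note), and the
#' ORIGIN sequence block. \code{\link{readGenBank}} round-trips it.
#'
#' @param record an \code{\link{AnnotatedRecord}}.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeGenBank <- function(record, path) {
  stopifnot(is(record, "AnnotatedRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(record@seq)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
                     gsub("\\s", "_", record@name), n,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", record@name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- record@features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (!is.null(f$strand) && f$strand[i] == "-")
      loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", "misc_feature", loc), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    if (!is.null(f$note) && !is.na(f$note[i]) && nzchar(f$note[i]))
      writeLines(sprintf("                     /note=\"%s\"", f$note[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record@seq)
  for (start in seq(1L, n, by = 60L)) {
    chunk <- substr(s, start, min(start + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", start, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by writeGenBank
#' @param path GenBank file.
#' @return an \code{\link{AnnotatedRecord}}.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  name <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grepl("^LOCUS", lines)][1])
  oi <- which(lines == "ORIGIN")
  seq <- toupper(gsub("[^acgtn]", "",
                      paste(lines[(oi + 1L):(length(lines))], collapse = "")))
  featLines <- lines[seq_len(oi - 1L)]
  idx <- grep("^     misc_feature", featLines)
  feats <- lapply(idx, function(i) {
    loc <- sub("^\\s*misc_feature\\s+", "", featLines[i])
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
    lab <- sub('.*?/label="([^"]*)".*', "\\1", featLines[i + 1L])
    data.frame(label = lab, start = nums[1], end = nums[2], strand = strand,
               stringsAsFactors = FALSE)
  })
  AnnotatedRecord(name, seq,
                  if (length(feats)) do.call(rbind, feats) else data.frame())
}
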