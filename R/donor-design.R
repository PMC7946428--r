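## Switch-and-flip donor construction.
##
## Donor layout, 5' -> 3':
##   rc(guide2 footprint) | arm1 = locus(cut1, insertion] | linker5+tag+linker3
##   | arm2 = locus(insertion, cut2] | rc(guide1 footprint)
## where each "footprint" is the 23-nt protospacer+PAM as read on the locus
## sense strand. This placement makes reverse-orientation insertions
## regenerate both original intact target sites (so Cas9 cuts them out
## again), while forward insertions destroy both sites.

#' Resolve the cassette insertion point on the locus
#'
#' Returns the locus coordinate of the last base kept before the cassette:
#' the final base of the last signal-peptide codon (after_signal_peptide),
#' of the start codon (n_terminal; preserves the initiator Met), or of the
#' user-chosen codon (custom_offset). The returned coordinate is always on a
#' codon boundary of the CDS by construction.
#'
#' @param model a \code{\link{GeneModel}}.
#' @param cassette a \code{\link{TagCassette}}.
#' @return integer locus coordinate (cassette goes after this base).
#' @export
resolveInsertionPoint <- function(model, cassette) {
  validObject(cassette)
  nCodons <- switch(cassette@insertionMode,
    after_signal_peptide = cassette@signalPeptideAA,
    n_terminal = 1L,
    custom_offset = cassette@customOffsetAA)
  if (nCodons < 1L) stop("frame error: insertion offset must be >= 1 codon")
  p <- model@cdsStart - 1L + 3L * nCodons
  ex <- model@exons
  host <- which(model@cdsStart >= IRanges::start(ex) &
                model@cdsStart <= IRanges::end(ex))
  if (!length(host) || p > IRanges::end(ex[host[1]]))
    stop("frame error: insertion point crosses an exon boundary")
  if (p >= model@cdsEnd)
    stop("frame error: insertion point beyond the CDS")
  as.integer(p)
}

#' Build the switch-and-flip donor
#'
#' Assembles the donor sequence from the guide pair, the genomic arms and the
#' tag cassette, and emits the component feature map. Total length is
#' 46 + (cut2 - cut1) + cassette length: the two 23-nt flipped end sites plus
#' the excised genomic span with the cassette added at the insertion point.
#'
#' @param locus locus DNA (named or plain character).
#' @param pair a \code{\link{GuidePair}} on this locus.
#' @param cassette a \code{\link{TagCassette}}.
#' @param insertionPoint coordinate from \code{\link{resolveInsertionPoint}};
#'   must lie strictly between the two cuts.
#' @return a \code{\link{DonorDesign}}.
#' @export
buildDonor <- function(locus, pair, cassette, insertionPoint) {
  seq <- assertDNA(unname(locus)[1], "locus")
  validObject(pair); validObject(cassette)
  c1 <- cutUpstream(pair); c2 <- cutDownstream(pair)
  if (insertionPoint <= c1 || insertionPoint >= c2)
    stop("insertion outside excision: insertion point must lie strictly ",
         "between the cuts (", c1, ", ", c2, ")")
  if (pair@downstream$end > nchar(seq) || pair@upstream$start < 1L)
    stop("pair invariant violation: footprint outside locus")

  upFoot <- substr(seq, pair@upstream$start, pair@upstream$end)
  dnFoot <- substr(seq, pair@downstream$start, pair@downstream$end)
  arm1 <- substr(seq, c1 + 1L, insertionPoint)
  arm2 <- substr(seq, insertionPoint + 1L, c2)
  ins <- cassetteSeq(cassette)
  donor <- paste0(revComp(dnFoot), arm1, ins, arm2, revComp(upFoot))

  b <- cumsum(c(23L, nchar(arm1), nchar(ins), nchar(arm2), 23L))
  features <- data.frame(
    label = c("flipped_site2", "arm1", "cassette", "arm2", "flipped_site1"),
    start = c(1L, b[1] + 1L, b[2] + 1L, b[3] + 1L, b[4] + 1L),
    end = b,
    strand = c("-", "+", "+", "+", "-"),
    stringsAsFactors = FALSE)

  new("DonorDesign", pair = pair, donorSeq = donor, features = features,
      insertionPoint = as.integer(insertionPoint), cassette = cassette,
      locusName = names(locus) %||% "locus")
}

#' Annotate a donor design as a GenBank-ready record
#'
#' Emits the five component features plus guide/PAM sub-features for the two
#' flipped end sites. The component features tile the donor exactly; the
#' cassette feature carries a frame=0 note.
#'
#' @param design a \code{\link{DonorDesign}}.
#' @return an \code{\link{AnnotatedRecord}}.
#' @export
annotateDonor <- function(design) {
  f <- design@features
  f$note <- ifelse(f$label == "cassette",
                   paste0("frame=0;tag=", design@cassette@tagName), "")
  D <- nchar(design@donorSeq)
  # Reverse-complementing a footprint swaps the PAM end: a plus-strand
  # genomic guide has its PAM at positions 1..3 of the flipped copy, a
  # minus-strand guide at 21..23.
  site2PamLeft <- design@pair@downstream$strand == "+"
  site1PamLeft <- design@pair@upstream$strand == "+"
  sub <- data.frame(
    label = c("guide2_pam", "guide2_protospacer",
              "guide1_pam", "guide1_protospacer"),
    start = c(if (site2PamLeft) 1L else 21L,
              if (site2PamLeft) 4L else 1L,
              if (site1PamLeft) D - 22L else D - 2L,
              if (site1PamLeft) D - 19L else D - 22L),
    end = c(if (site2PamLeft) 3L else 23L,
            if (site2PamLeft) 23L else 20L,
            if (site1PamLeft) D - 20L else D,
            if (site1PamLeft) D else D - 3L),
    strand = "-", note = "", stringsAsFactors = FALSE)
  AnnotatedRecord(paste0(design@locusName, "_donor"), design@donorSeq,
                  rbind(f, sub))
}

#' Design summary as a plain list (JSON-ready)
#' @param design a \code{\link{DonorDesign}}.
#' @return list of design facts.
#' @export
designSummary <- function(design) {
  list(
    locus = design@locusName,
    tag = design@cassette@tagName,
    insertion_mode = design@cassette@insertionMode,
    insertion_point = design@insertionPoint,
    cut_upstream = cutUpstream(design@pair),
    cut_downstream = cutDownstream(design@pair),
    guide1_start = design@pair@upstream$start,
    guide1_strand = design@pair@upstream$strand,
    guide2_start = design@pair@downstream$start,
    guide2_strand = design@pair@downstream$strand,
    excised_len = design@pair@excisedLen,
    donor_len = nchar(design@donorSeq),
    cassette_len = nchar(cassetteSeq(design@cassette)),
    cassette_frame = 0L,
    guide1 = design@pair@upstream$protospacer,
    guide1_pam = design@pair@upstream$pam,
    guide2 = design@pair@downstream$protospacer,
    guide2_pam = design@pair@downstream$pam,
    pair_score = design@pair@pairScore)
}
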