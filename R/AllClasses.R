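#' @importClassesFrom IRanges IRanges
NULL

## ---- GeneModel --------------------------------------------------------------

#' GeneModel: exon/intron/UTR/CDS structure of one gene on a locus sequence
#'
#' Coordinates are 1-based closed intervals on the *sense strand* of the
#' extracted locus: minus-strand genes are normalised at load time
#' (\code{\link{loadLocus}}), so every downstream module sees a plus-strand
#' gene. The \code{origin} slot retains the genomic frame (chromosome, span,
#' native strand) so coordinates can be mapped back.
#'
#' @slot geneId gene identifier.
#' @slot chrom source sequence name.
#' @slot strand native strand of the gene on the source genome ("+" or "-").
#' @slot exons \code{IRanges} of exons, ordered 5' to 3' on the sense strand.
#' @slot cdsStart,cdsEnd first and last CDS base (sense locus coordinates).
#' @slot origin list with \code{start}, \code{end}, \code{width} of the
#'   extracted window on the native genome (used for coordinate round-trips).
#' @export
setClass("GeneModel", representation(
  geneId = "character",
  chrom = "character",
  strand = "character",
  exons = "IRanges",
  cdsStart = "integer",
  cdsEnd = "integer",
  origin = "list"
))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msgs <- character(0)
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(ex) < 1L)
    msgs <- c(msgs, "at least one exon required")
  if (is.unsorted(IRanges::start(ex), strictly = TRUE))
    msgs <- c(msgs, "exons must be sorted by start")
  if (length(ex) > 1L &&
      any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
    msgs <- c(msgs, "exons must be non-overlapping with introns of length >= 1")
  if (object@cdsEnd < object@cdsStart)
    msgs <- c(msgs, "cdsEnd < cdsStart")
  else {
    inExon <- function(p) any(p >= IRanges::start(ex) & p <= IRanges::end(ex))
    if (!inExon(object@cdsStart) || !inExon(object@cdsEnd))
      msgs <- c(msgs, "CDS boundaries must fall inside exons")
  }
  if (length(msgs)) msgs else TRUE
})

# Internal gaps (introns) of a sorted exon set.
gaps_internal <- function(ex) {
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(IRanges::end(ex)[-length(ex)] + 1L,
                   IRanges::start(ex)[-1L] - 1L)
}

#' Construct a GeneModel
#'
#' @param geneId,chrom,strand,exons,cdsStart,cdsEnd,origin see class slots.
#' @return a \code{GeneModel}.
#' @export
GeneModel <- function(geneId, chrom, strand, exons, cdsStart, cdsEnd,
                      origin = list()) {
  new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
      exons = exons, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd), origin = origin)
}

#' @describeIn GeneModel exon ranges (IRanges, sense coordinates)
#' @param x a GeneModel
#' @export
exons <- function(x) x@exons

#' @describeIn GeneModel intron ranges derived from exons
#' @export
introns <- function(x) gaps_internal(x@exons)

#' @describeIn GeneModel 5'UTR intervals (exonic sequence before the CDS)
#' @export
utr5 <- function(x) {
  IRanges::intersect(IRanges::IRanges(1L, x@cdsStart - 1L), x@exons)
}

#' @describeIn GeneModel 3'UTR intervals (exonic sequence after the CDS)
#' @export
utr3 <- function(x) {
  e <- max(IRanges::end(x@exons))
  if (x@cdsEnd >= e) return(IRanges::IRanges())
  IRanges::intersect(IRanges::IRanges(x@cdsEnd + 1L, e), x@exons)
}

#' @describeIn GeneModel CDS interval boundaries c(start, end)
#' @export
cdsSpan <- function(x) c(x@cdsStart, x@cdsEnd)

#' @describeIn GeneModel interior splice-junction boundary positions: for each
#'   junction, the last base of the upstream exon and the first base of the
#'   downstream exon.
#' @export
spliceJunctions <- function(x) {
  ex <- x@exons
  if (length(ex) < 2L) return(integer(0))
  sort(c(IRanges::end(ex)[-length(ex)], IRanges::start(ex)[-1L]))
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", object@geneId, "(", object@chrom, object@strand, ")\n")
  cat("  exons:", length(object@exons), "| CDS:", object@cdsStart, "-",
      object@cdsEnd, "| locus width:",
      max(IRanges::end(object@exons)), "+\n")
})

## ---- TagCassette ------------------------------------------------------------

#' TagCassette: the in-frame insert (linker5 + tag + linker3)
#'
#' @slot tagName label, e.g. "SEP", "GFP", "myc".
#' @slot tagSeq tag coding sequence, length divisible by 3, no in-frame stop.
#' @slot linker5,linker3 linker coding sequences (may be ""), same rules.
#' @slot insertionMode one of "after_signal_peptide", "n_terminal",
#'   "custom_offset".
#' @slot signalPeptideAA signal-peptide length in amino acids
#'   (after_signal_peptide mode).
#' @slot customOffsetAA amino-acid offset from the start codon
#'   (custom_offset mode).
#' @export
setClass("TagCassette", representation(
  tagName = "character", tagSeq = "character",
  linker5 = "character", linker3 = "character",
  insertionMode = "character",
  signalPeptideAA = "integer", customOffsetAA = "integer"
))

setValidity("TagCassette", function(object) {
  msgs <- character(0)
  parts <- c(object@linker5, object@tagSeq, object@linker3)
  full <- paste(parts, collapse = "")
  if (nchar(object@tagSeq) < 3L) msgs <- c(msgs, "tag sequence too short")
  if (any(nchar(parts) %% 3L != 0L))
    msgs <- c(msgs, "tag and linker lengths must be divisible by 3")
  else if (grepl("\\*", translateCDS(full, toStop = FALSE)))
    msgs <- c(msgs, "cassette contains an in-frame stop codon")
  if (!object@insertionMode %in%
      c("after_signal_peptide", "n_terminal", "custom_offset"))
    msgs <- c(msgs, "unknown insertion mode")
  if (object@insertionMode == "after_signal_peptide" &&
      object@signalPeptideAA < 1L)
    msgs <- c(msgs, "after_signal_peptide mode needs signalPeptideAA > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TagCassette
#'
#' @param tagName label for reports.
#' @param tagSeq in-frame tag coding DNA.
#' @param linker5,linker3 in-frame linkers (default none). The method leaves
#'   linker choice to the user; none are hard-coded.
#' @param insertionMode where the cassette goes: right after the signal
#'   peptide (membrane/secreted proteins), right after the start codon
#'   ("n_terminal", preserves the initiator Met, suited to cytosolic proteins),
#'   or at a custom codon offset.
#' @param signalPeptideAA signal peptide length (aa), required for
#'   after_signal_peptide.
#' @param customOffsetAA codon offset from the start codon for custom_offset.
#' @return a \code{TagCassette}.
#' @export
TagCassette <- function(tagName, tagSeq, linker5 = "", linker3 = "",
                        insertionMode = c("after_signal_peptide",
                                          "n_terminal", "custom_offset"),
                        signalPeptideAA = 0L, customOffsetAA = 0L) {
  insertionMode <- match.arg(insertionMode)
  new("TagCassette", tagName = tagName,
      tagSeq = if (nzchar(tagSeq)) assertDNA(tagSeq, "tag") else tagSeq,
      linker5 = if (nzchar(linker5)) assertDNA(linker5, "linker5") else "",
      linker3 = if (nzchar(linker3)) assertDNA(linker3, "linker3") else "",
      insertionMode = insertionMode,
      signalPeptideAA = as.integer(signalPeptideAA),
      customOffsetAA = as.integer(customOffsetAA))
}

#' @describeIn TagCassette full insert sequence linker5+tag+linker3
#' @param x a TagCassette
#' @export
cassetteSeq <- function(x) paste0(x@linker5, x@tagSeq, x@linker3)

setMethod("show", "TagCassette", function(object) {
  cat("TagCassette:", object@tagName, "|", nchar(cassetteSeq(object)),
      "bp insert | mode:", object@insertionMode, "\n")
})

## ---- GuidePair --------------------------------------------------------------

#' GuidePair: an upstream/downstream pair of SpCas9 cut sites
#'
#' Both sites are one-row guide-site tables as returned by
#' \code{\link{scanPamSites}}. The upstream cut must lie 5' of the downstream
#' cut, and the excised interval must contain the coding span being replaced.
#'
#' @slot upstream,downstream one-row data.frames (guide-site schema).
#' @slot excisedLen excised length in bp (cut to cut).
#' @slot pairScore min of the two on-target scores.
#' @export
setClass("GuidePair", representation(
  upstream = "data.frame", downstream = "data.frame",
  excisedLen = "integer", pairScore = "numeric"
))

setValidity("GuidePair", function(object) {
  if (nrow(object@upstream) != 1L || nrow(object@downstream) != 1L)
    return("upstream and downstream must be single guide-site rows")
  if (object@upstream$cutPos >= object@downstream$cutPos)
    return("upstream cut must be 5' of downstream cut")
  TRUE
})

#' Construct a GuidePair from two guide-site rows
#' @param upstream,downstream one-row guide-site data.frames.
#' @return a \code{GuidePair}.
#' @export
GuidePair <- function(upstream, downstream) {
  new("GuidePair", upstream = as.data.frame(upstream),
      downstream = as.data.frame(downstream),
      excisedLen = as.integer(downstream$cutPos - upstream$cutPos),
      pairScore = min(upstream$onScore, downstream$onScore))
}

#' @describeIn GuidePair blunt-cut coordinate of the upstream guide (last base
#'   kept on the left fragment)
#' @param x a GuidePair
#' @export
cutUpstream <- function(x) x@upstream$cutPos

#' @describeIn GuidePair blunt-cut coordinate of the downstream guide
#' @export
cutDownstream <- function(x) x@downstream$cutPos

setMethod("show", "GuidePair", function(object) {
  cat("GuidePair: cuts", object@upstream$cutPos, "/",
      object@downstream$cutPos, "| excised", object@excisedLen,
      "bp | score", format(object@pairScore, digits = 3), "\n")
})

## ---- DonorDesign ------------------------------------------------------------

#' DonorDesign: the switch-and-flip donor
#'
#' The donor carries, 5' to 3': the reverse complement of the downstream
#' (guide 2) 23-nt protospacer+PAM footprint; the genomic arm from the
#' upstream cut to the insertion point; the tag cassette; the genomic arm from
#' the insertion point to the downstream cut; and the reverse complement of
#' the upstream (guide 1) footprint. The flipped ends make the donor itself a
#' Cas9 substrate (excisable from its plasmid) and make reverse-orientation
#' genomic insertions regenerate both original target sites, so they are cut
#' again.
#'
#' @slot pair the \code{GuidePair} used.
#' @slot donorSeq full donor sequence.
#' @slot features data.frame (label, start, end, strand) tiling the donor.
#' @slot insertionPoint locus coordinate after which the cassette is inserted.
#' @slot cassette the \code{TagCassette}.
#' @slot locusName name of the locus sequence the arms came from.
#' @export
setClass("DonorDesign", representation(
  pair = "GuidePair", donorSeq = "character", features = "data.frame",
  insertionPoint = "integer", cassette = "TagCassette", locusName = "character"
))

#' @describeIn DonorDesign the donor sequence
#' @param x a DonorDesign
#' @export
donorSeq <- function(x) x@donorSeq

#' @describeIn DonorDesign the annotated feature table
#' @export
donorFeatures <- function(x) x@features

setMethod("show", "DonorDesign", function(object) {
  cat("DonorDesign:", nchar(object@donorSeq), "bp |",
      object@cassette@tagName, "cassette at locus pos",
      object@insertionPoint, "\n")
  print(object@features)
})

## ---- EditOutcome ------------------------------------------------------------

#' EditOutcome: one simulated allele
#'
#' @slot alleleSeq edited locus sequence.
#' @slot orientation "forward", "reverse", "none_ko" or "unedited".
#' @slot junctions data.frame (pos, description, bp) of ligation junctions
#'   and any INDELs applied there.
#' @slot intactSites data.frame of re-found intact 23-nt target sites.
#' @slot mrna predicted mature mRNA ("" when splice mapping fails).
#' @slot protein predicted protein ("" when no ORF).
#' @slot classification "KI", "recuttable", "KO" or "WT".
#' @export
setClass("EditOutcome", representation(
  alleleSeq = "character", orientation = "character",
  junctions = "data.frame", intactSites = "data.frame",
  mrna = "character", protein = "character", classification = "character"
))

#' @describeIn EditOutcome the edited allele sequence
#' @param x an EditOutcome
#' @export
alleleSeq <- function(x) x@alleleSeq

#' @describeIn EditOutcome the predicted protein
#' @export
outcomeProtein <- function(x) x@protein

#' @describeIn EditOutcome the classification label
#' @export
classification <- function(x) x@classification

setMethod("show", "EditOutcome", function(object) {
  cat("EditOutcome:", object@orientation, "->", object@classification,
      "|", nchar(object@alleleSeq), "bp allele |",
      nrow(object@intactSites), "intact target site(s)\n")
})

## ---- FrapTrace / FrapFit ----------------------------------------------------

#' FrapTrace: a normalized fluorescence-recovery trace
#'
#' Normalisation convention: pre-bleach mean = 1, first post-bleach value = 0.
#'
#' @slot t acquisition times in minutes (uniform grid).
#' @slot f normalized intensities.
#' @slot bleachIndex index of the first post-bleach point.
#' @export
setClass("FrapTrace", representation(
  t = "numeric", f = "numeric", bleachIndex = "integer"
))

setValidity("FrapTrace", function(object) {
  msgs <- character(0)
  if (length(object@t) != length(object@f))
    msgs <- c(msgs, "t and f lengths differ")
  if (object@bleachIndex < 3L)
    msgs <- c(msgs, "need >= 2 pre-bleach points")
  if (length(object@f) - object@bleachIndex + 1L < 4L)
    msgs <- c(msgs, "need >= 4 post-bleach points")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FrapTrace
#' @param t,f,bleachIndex see class slots.
#' @return a \code{FrapTrace}.
#' @export
FrapTrace <- function(t, f, bleachIndex) {
  new("FrapTrace", t = as.numeric(t), f = as.numeric(f),
      bleachIndex = as.integer(bleachIndex))
}

setMethod("show", "FrapTrace", function(object) {
  cat("FrapTrace:", length(object@t), "points, bleach at index",
      object@bleachIndex, "\n")
})

#' FrapFit: one-phase-decay fit of a FRAP trace
#'
#' Model: f(t') = plateau * (1 - exp(-t'/tau)) for post-bleach time t'.
#' The plateau is the mobile fraction; immobile fraction = 1 - plateau.
#'
#' @slot tau recovery time constant (minutes).
#' @slot plateau fitted plateau (mobile fraction).
#' @slot immobileFrac 1 - plateau.
#' @slot residualRMS root-mean-square fit residual.
#' @slot flagged TRUE when plateau > 1 (soft bound).
#' @export
setClass("FrapFit", representation(
  tau = "numeric", plateau = "numeric", immobileFrac = "numeric",
  residualRMS = "numeric", flagged = "logical"
))

setMethod("show", "FrapFit", function(object) {
  cat(sprintf(
    "FrapFit: tau = %.4g min | mobile = %.4g | immobile = %.2f%%%s\n",
    object@tau, object@plateau, 100 * object@immobileFrac,
    if (object@flagged) " [plateau > 1]" else ""))
})

#' @describeIn FrapFit recovery time constant in minutes
#' @param x a FrapFit
#' @export
frapTau <- function(x) x@tau

#' @describeIn FrapFit immobile fraction (0..1 scale)
#' @export
immobileFrac <- function(x) x@immobileFrac
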