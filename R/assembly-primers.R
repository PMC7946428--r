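## Cloning-primer generation.
##
## Two jobs: (1) the expedited four-fragment HiFi assembly that puts two U6
## guide cassettes into a pX330-style vector, using fixed template primers
## (lower case = fixed vector-side flank, upper case = guide-dependent
## region, case preserved for readability; comparisons are case-insensitive);
## (2) homology-arm primers for the three-fragment donor assembly.

# Fixed template strings for the four-fragment guide-vector assembly.
GUIDE_TEMPLATES <- list(
  common_F = "tggccttttgctggccttttgctcacatgtGAGGGCCTATTTCCCATG",
  frag2_R_5 = "tagctctaaaac",
  frag2_R_3 = "CGGTGTTTCGTCCTTTCCAC",
  frag3_F_5 = "aggacgaaacaccG",
  frag3_F_3 = "GTTTTAGAGCTAGAAATAGCAAGTTaaaataag",
  frag4_F_3 = "GTTTTAGAGCTAGAAATAGCAAG",
  common_R = "ccatttaccgtaagttatgtaacgggtaccgatatctagaaaaaagcaccg")

#' GuideCloningSet: the six primers of the four-fragment guide-vector assembly
#'
#' @slot guide1,guide2 the 20-nt guides.
#' @slot primers data.frame (name, seq, role, length, tm).
#' @slot nFill1,nFill2 filled-N count per guide: 19 for a G-start guide
#'   (the template's fixed base supplies the U6-required G), 20 otherwise.
#' @export
setClass("GuideCloningSet", representation(
  guide1 = "character", guide2 = "character", primers = "data.frame",
  nFill1 = "integer", nFill2 = "integer"
))

setMethod("show", "GuideCloningSet", function(object) {
  cat("GuideCloningSet: guide1", object@guide1, "( fill", object@nFill1,
      "N ) guide2", object@guide2, "( fill", object@nFill2, "N )\n")
  print(object@primers[, c("name", "length", "tm")])
})

checkGuide20 <- function(guide) {
  guide <- assertDNA(guide, "guide")
  if (nchar(guide) != 20L) stop("guide length must be 20 nt")
  guide
}

#' Antisense fill for the custom reverse primers
#'
#' The filled region is the guide antisense strand ending with C. For a
#' G-start guide the template's fixed flanking C completes the pair, so the
#' final C is dropped (19 N); otherwise a G is prepended to the guide before
#' reverse-complementing and the final base dropped (20 N), so the U6
#' cassette always transcribes a G-start guide.
#'
#' @param guide 20-nt guide sequence.
#' @return 19- or 20-nt fill string.
#' @export
fillAntisense <- function(guide) {
  guide <- checkGuide20(guide)
  src <- if (startsWith(guide, "G")) guide else paste0("G", guide)
  rc <- revComp(src)
  substr(rc, 1L, nchar(rc) - 1L)
}

#' Sense fill for the custom forward primers
#'
#' The filled region is the guide sense strand beginning with G; the
#' template's fixed G supplies the leading base, so a G-start guide drops its
#' own leading G (19 N) and any other guide is used verbatim (20 N).
#'
#' @param guide 20-nt guide sequence.
#' @return 19- or 20-nt fill string.
#' @export
fillSense <- function(guide) {
  guide <- checkGuide20(guide)
  if (startsWith(guide, "G")) substr(guide, 2L, 20L) else guide
}

#' Primers for the expedited four-fragment guide-vector assembly
#'
#' Returns the two fixed primers and the four guide-filled primers; the fixed
#' flanks are byte-identical to the templates (including case).
#'
#' @param guide1,guide2 20-nt guide sequences.
#' @return a \code{\link{GuideCloningSet}}.
#' @export
guideVectorPrimers <- function(guide1, guide2) {
  guide1 <- checkGuide20(guide1); guide2 <- checkGuide20(guide2)
  tpl <- GUIDE_TEMPLATES
  seqs <- c(
    common_F = tpl$common_F,
    frag2_R = paste0(tpl$frag2_R_5, fillAntisense(guide1), tpl$frag2_R_3),
    frag3_F = paste0(tpl$frag3_F_5, fillSense(guide1), tpl$frag3_F_3),
    frag3_R = paste0(tpl$frag2_R_5, fillAntisense(guide2), tpl$frag2_R_3),
    frag4_F = paste0(tpl$frag3_F_5, fillSense(guide2), tpl$frag4_F_3),
    common_R = tpl$common_R)
  primers <- data.frame(
    name = names(seqs), seq = unname(seqs), role = names(seqs),
    length = nchar(unname(seqs)), tm = wallaceTm(unname(seqs)),
    stringsAsFactors = FALSE)
  new("GuideCloningSet", guide1 = guide1, guide2 = guide2, primers = primers,
      nFill1 = nchar(fillAntisense(guide1)),
      nFill2 = nchar(fillAntisense(guide2)))
}

# 5'->3' annealing region starting at `from` on `template`, extended until
# the Wallace-rule Tm reaches `tmTarget`, between minLen and maxLen nt.
annealRegion <- function(template, from, tmTarget = 60, minLen = 18L,
                         maxLen = 35L) {
  avail <- nchar(template) - from + 1L
  if (avail < minLen) stop("fragment too short for an annealing region")
  len <- minLen
  while (len < min(maxLen, avail) &&
         wallaceTm(substr(template, from, from + len - 1L)) < tmTarget)
    len <- len + 1L
  substr(template, from, from + len - 1L)
}

#' Homology-arm primers for the three-fragment donor assembly
#'
#' Fragment 1 = flipped guide-2 site + upstream genomic arm, fragment 2 = the
#' tag cassette, fragment 3 = downstream genomic arm + flipped guide-1 site.
#' Each forward primer (fragments 2 and 3) carries an \code{overlap}-bp 5'
#' tail copied from the end of the preceding fragment, so adjacent amplicons
#' share exactly \code{overlap} bp and HiFi/Gibson assembly reconstructs the
#' donor. Optional vector arms add tails at the two outer ends. Annealing
#' regions are extended until the Wallace-rule estimate reaches 60 C (18-35
#' nt).
#'
#' @param design a \code{\link{DonorDesign}}.
#' @param overlap homology length in bp (15-40, default 25).
#' @param vectorArm5,vectorArm3 optional backbone homology tails for the two
#'   outer junctions ("" = none; supply your linearised-vector end sequences
#'   for real cloning).
#' @return list with \code{primers} (data.frame: name, seq, role, length,
#'   tm) and \code{amplicons} (the three simulated PCR products including
#'   tails).
#' @export
donorAssemblyPrimers <- function(design, overlap = 25L, vectorArm5 = "",
                                 vectorArm3 = "") {
  if (overlap < 15L || overlap > 40L)
    stop("overlap must be between 15 and 40 bp")
  donor <- design@donorSeq
  f <- design@features
  j1 <- f$end[f$label == "arm1"]        # fragment1 | fragment2 junction
  j2 <- f$end[f$label == "cassette"]    # fragment2 | fragment3 junction
  D <- nchar(donor)
  if (j1 < max(overlap, 18L) || j2 - j1 < 18L || D - j2 < 18L)
    stop("fragment too short for overlap + annealing region")

  frag1 <- substr(donor, 1L, j1)
  frag2 <- substr(donor, j1 + 1L, j2)
  frag3 <- substr(donor, j2 + 1L, D)

  tail2 <- substr(donor, j1 - overlap + 1L, j1)
  tail3 <- substr(donor, j2 - overlap + 1L, j2)

  p <- list(
    frag1_F = paste0(vectorArm5, annealRegion(frag1, 1L)),
    frag1_R = annealRegion(revComp(frag1), 1L),
    frag2_F = paste0(tail2, annealRegion(frag2, 1L)),
    frag2_R = annealRegion(revComp(frag2), 1L),
    frag3_F = paste0(tail3, annealRegion(frag3, 1L)),
    frag3_R = paste0(if (nzchar(vectorArm3)) revComp(vectorArm3) else "",
                     annealRegion(revComp(frag3), 1L)))
  primers <- data.frame(
    name = names(p), seq = unname(unlist(p)),
    role = "donor_fragment_primer",
    length = nchar(unname(unlist(p))), tm = wallaceTm(unname(unlist(p))),
    stringsAsFactors = FALSE)
  amplicons <- c(
    frag1 = paste0(vectorArm5, frag1),
    frag2 = paste0(tail2, frag2),
    frag3 = paste0(tail3, frag3, vectorArm3))
  list(primers = primers, amplicons = amplicons)
}

#' Merge two fragments by their shared end/start overlap
#'
#' Finds the longest suffix of \code{a} equal (case-insensitively) to a
#' prefix of \code{b} and joins the two; errors below \code{minOverlap}.
#' This is the in-silico counterpart of HiFi/Gibson assembly.
#'
#' @param a,b DNA strings.
#' @param minOverlap minimum acceptable overlap (default 12 bp).
#' @return merged string (case of \code{a} kept over the overlap).
#' @export
mergeByOverlap <- function(a, b, minOverlap = 12L) {
  au <- toupper(a); bu <- toupper(b)
  maxL <- min(nchar(au), nchar(bu))
  for (L in seq(maxL, minOverlap)) {
    if (substr(au, nchar(au) - L + 1L, nchar(au)) == substr(bu, 1L, L))
      return(paste0(a, substr(b, L + 1L, nchar(b))))
  }
  stop("assembly failed: no terminal overlap >= ", minOverlap, " bp")
}

#' Assemble an ordered set of fragments, optionally circularising
#'
#' @param fragments character vector of fragments in assembly order.
#' @param minOverlap minimum overlap per junction.
#' @param circular if TRUE, the final product's terminal overlap with its own
#'   start is removed (one circular sequence), and an error is raised when
#'   the ends do not overlap.
#' @return assembled sequence.
#' @export
assembleFragments <- function(fragments, minOverlap = 12L, circular = FALSE) {
  out <- Reduce(function(a, b) mergeByOverlap(a, b, minOverlap), fragments)
  if (circular) {
    ou <- toupper(out)
    maxL <- min(nchar(ou) %/% 2L, 200L)
    done <- FALSE
    for (L in seq(maxL, minOverlap)) {
      if (substr(ou, nchar(ou) - L + 1L, nchar(ou)) == substr(ou, 1L, L)) {
        out <- substr(out, 1L, nchar(out) - L)
        done <- TRUE
        break
      }
    }
    if (!done) stop("assembly failed: ends do not circularise")
  }
  out
}

#' Primer order sheet
#' @param primers data.frame of primers (or a \code{GuideCloningSet}).
#' @param path output TSV path.
#' @return path, invisibly.
#' @export
writePrimerSheet <- function(primers, path) {
  if (is(primers, "GuideCloningSet")) primers <- primers@primers
  write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
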