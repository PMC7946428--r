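## Cas9 edit-outcome simulation.
##
## NHEJ is modelled as blunt, orientation-chosen ligation (no resection, no
## microhomology), optionally followed by seeded junction INDELs. Repair
## kinetics are not modelled; the deterministic outcome set
## {forward, reverse, none_ko, unedited} plus the re-cut flag captures the
## switch-and-flip logic: reverse insertions regenerate both target sites
## and stay Cas9 substrates, forward insertions destroy both.

# Blunt-cut offset within a 23-nt footprint as written on the sense strand:
# after base 17 for a plus-strand guide (PAM right), after base 6 for a
# minus-strand guide (PAM left).
footprintCutOffset <- function(strand) if (strand == "+") 17L else 6L

#' Cut the locus with a guide pair
#'
#' @param locus locus DNA string.
#' @param pair a \code{\link{GuidePair}}.
#' @return list(left, excised, right); their concatenation restores the locus.
#' @export
cutLocus <- function(locus, pair) {
  seq <- assertDNA(unname(locus)[1], "locus")
  validObject(pair)
  c1 <- cutUpstream(pair); c2 <- cutDownstream(pair)
  if (c1 < 1L || c2 > nchar(seq))
    stop("pair invariant violation: cuts outside locus")
  list(left = substr(seq, 1L, c1),
       excised = substr(seq, c1 + 1L, c2),
       right = substr(seq, c2 + 1L, nchar(seq)))
}

#' Release the donor fragment from its plasmid
#'
#' Locates the two flipped end sites on the plasmid, cuts each 3 bp from its
#' PAM, and returns the internal fragment. Depending on each guide's genomic
#' strand, a 6-nt or 17-nt stub of the flipped site stays on the fragment;
#' these stubs end up in non-coding DNA after insertion.
#'
#' @param plasmid DNA string containing the donor exactly once.
#' @param design the \code{\link{DonorDesign}}.
#' @return the released DNA fragment (character).
#' @export
releaseDonor <- function(plasmid, design) {
  plasmid <- assertDNA(unname(plasmid)[1], "plasmid")
  donor <- design@donorSeq
  p <- gregexpr(donor, plasmid, fixed = TRUE)[[1]]
  if (p[1] == -1L || length(p) != 1L)
    stop("donor sites ambiguous: donor not found exactly once in plasmid")
  flipped2 <- substr(donor, 1L, 23L)
  flipped1 <- substr(donor, nchar(donor) - 22L, nchar(donor))
  countOcc <- function(x) {
    m <- gregexpr(x, plasmid, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  if (countOcc(flipped2) != 1L || countOcc(flipped1) != 1L)
    stop("donor sites ambiguous: flipped end site absent or repeated")
  # cut offsets inside the flipped copies mirror the genomic geometry
  off2 <- 23L - footprintCutOffset(design@pair@downstream$strand)
  off1 <- 23L - footprintCutOffset(design@pair@upstream$strand)
  fragStart <- p + off2            # first base kept after the left cut
  fragEnd <- p + nchar(donor) - 23L + off1 - 1L
  substr(plasmid, fragStart, fragEnd)
}

#' Ligate the released fragment into the cut locus
#'
#' Blunt ligation in the requested orientation; no bases are gained or lost
#' beyond the fragment itself.
#'
#' @param left,right arms from \code{\link{cutLocus}}.
#' @param fragment released donor fragment.
#' @param orientation "forward" or "reverse".
#' @return an \code{\link{EditOutcome}} (allele and junctions only; transcript
#'   prediction and classification are added by
#'   \code{\link{predictTranscript}} / \code{\link{classifyOutcome}}).
#' @export
insertFragment <- function(left, right, fragment,
                           orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  frag <- if (orientation == "forward") fragment else revComp(fragment)
  allele <- paste0(left, frag, right)
  junctions <- data.frame(
    pos = c(nchar(left), nchar(left) + nchar(frag)),
    description = c("left ligation junction", "right ligation junction"),
    bp = 0L, stringsAsFactors = FALSE)
  new("EditOutcome", alleleSeq = allele, orientation = orientation,
      junctions = junctions, intactSites = data.frame(),
      mrna = "", protein = "", classification = "")
}

#' Religate the cut locus without the donor (knock-out path)
#'
#' @param left,right arms from \code{\link{cutLocus}}.
#' @return an \code{\link{EditOutcome}} with orientation "none_ko".
#' @export
religateKO <- function(left, right) {
  allele <- paste0(left, right)
  new("EditOutcome", alleleSeq = allele, orientation = "none_ko",
      junctions = data.frame(pos = nchar(left),
                             description = "religation junction",
                             bp = 0L, stringsAsFactors = FALSE),
      intactSites = data.frame(), mrna = "", protein = "",
      classification = "")
}

#' Find intact original target sites on an allele
#'
#' Scans both strands for exact 23-nt matches to either original footprint.
#' Reverse-orientation insertions regenerate both sites; forward insertions
#' and religations generically destroy them.
#'
#' @param allele allele DNA string (or an \code{\link{EditOutcome}}).
#' @param pair the original \code{\link{GuidePair}} with footprints taken
#'   from the locus (columns start/end refer to the locus; the stored
#'   protospacer/pam strings are used for matching).
#' @param locus the original locus (source of the exact footprint strings).
#' @return data.frame (site, pos, strand) of intact matches.
#' @export
detectIntactSites <- function(allele, pair, locus) {
  if (is(allele, "EditOutcome")) allele <- allele@alleleSeq
  seq <- assertDNA(unname(locus)[1], "locus")
  feet <- c(upstream = substr(seq, pair@upstream$start, pair@upstream$end),
            downstream = substr(seq, pair@downstream$start,
                                pair@downstream$end))
  hits <- list()
  for (nm in names(feet)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") feet[[nm]] else revComp(feet[[nm]])
      m <- gregexpr(pat, allele, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (p in m)
        hits[[length(hits) + 1L]] <- data.frame(
          site = nm, pos = as.integer(p), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(site = character(0), pos = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$pos), , drop = FALSE]
}

#' Apply seeded random INDELs at ligation junctions
#'
#' At each junction, inserts or deletes up to \code{maxIndel} random bases,
#' reproducibly under \code{seed}. Deletions remove bases immediately left of
#' the junction. Junction positions of later junctions are shifted
#' accordingly in the returned record.
#'
#' @param outcome an \code{\link{EditOutcome}} (or plain allele string with
#'   \code{junctions} supplied).
#' @param maxIndel maximum INDEL size in bp (0 = identity).
#' @param seed RNG seed (required for reproducibility).
#' @param junctions optional junction table when \code{outcome} is a string.
#' @return the outcome with modified allele and junction records.
#' @export
applyJunctionIndels <- function(outcome, maxIndel, seed, junctions = NULL) {
  asObject <- is(outcome, "EditOutcome")
  allele <- if (asObject) outcome@alleleSeq else outcome
  jt <- if (asObject) outcome@junctions else junctions
  stopifnot(maxIndel >= 0L, !is.null(jt))
  if (maxIndel == 0L || !nrow(jt)) {
    if (asObject) return(outcome) else return(list(allele = allele,
                                                   junctions = jt))
  }
  withSeed(seed, {
    shift <- 0L
    for (i in seq_len(nrow(jt))) {
      pos <- jt$pos[i] + shift
      k <- sample.int(maxIndel + 1L, 1L) - 1L     # 0..maxIndel
      if (k == 0L) next
      if (runif(1) < 0.5) {                        # insertion
        ins <- randomDNA(k)
        allele <- paste0(substr(allele, 1L, pos), ins,
                         substr(allele, pos + 1L, nchar(allele)))
        jt$bp[i] <- k
        jt$description[i] <- paste0(jt$description[i], " +", k, "bp ins")
        shift <- shift + k
      } else {                                     # deletion (left of cut)
        del <- min(k, pos)
        allele <- paste0(substr(allele, 1L, pos - del),
                         substr(allele, pos + 1L, nchar(allele)))
        jt$bp[i] <- -del
        jt$description[i] <- paste0(jt$description[i], " -", del, "bp del")
        jt$pos[i] <- jt$pos[i] - del
        shift <- shift - del
      }
    }
    if (asObject) {
      outcome@alleleSeq <- allele
      outcome@junctions <- jt
      outcome
    } else list(allele = allele, junctions = jt)
  })
}

## ---- transcript / protein prediction ---------------------------------------

# Unique match of `anchor` in `x`; 0 if absent, -1 if multiple.
uniqueMatch <- function(anchor, x) {
  m <- gregexpr(anchor, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(0L)
  if (length(m) > 1L) return(-1L)
  as.integer(m[1])
}

#' Splice the wild-type locus into its mature mRNA
#' @param locus locus DNA string.
#' @param model the \code{\link{GeneModel}}.
#' @return list(mrna, cdsOffset) with the 1-based CDS start inside the mRNA.
#' @export
spliceWildType <- function(locus, model) {
  seq <- assertDNA(unname(locus)[1], "locus")
  ex <- model@exons
  pieces <- substring(seq, IRanges::start(ex), IRanges::end(ex))
  mrna <- paste(pieces, collapse = "")
  before <- 0L
  for (i in seq_along(ex)) {
    if (model@cdsStart >= IRanges::start(ex)[i] &&
        model@cdsStart <= IRanges::end(ex)[i]) {
      off <- before + model@cdsStart - IRanges::start(ex)[i] + 1L
      return(list(mrna = mrna, cdsOffset = off))
    }
    before <- before + IRanges::width(ex)[i]
  }
  stop("annotation inconsistent: CDS start not inside an exon")
}

#' Expected wild-type and tagged proteins for a design
#'
#' @param locus locus DNA string.
#' @param model the \code{\link{GeneModel}}.
#' @param cassette the \code{\link{TagCassette}}.
#' @param insertionPoint coordinate from \code{\link{resolveInsertionPoint}}.
#' @return list(wtProtein, taggedProtein, tagInsertAAPos).
#' @export
expectedProduct <- function(locus, model, cassette, insertionPoint) {
  wt <- spliceWildType(locus, model)
  wtProt <- translateCDS(substr(wt$mrna, wt$cdsOffset, nchar(wt$mrna)))
  nAA <- (insertionPoint - model@cdsStart + 1L) %/% 3L
  insAA <- translateCDS(cassetteSeq(cassette), toStop = FALSE)
  tagged <- paste0(substr(wtProt, 1L, nAA), insAA,
                   substr(wtProt, nAA + 1L, nchar(wtProt)))
  list(wtProtein = wtProt, taggedProtein = tagged, tagInsertAAPos = nAA)
}

#' Splice-aware transcript and protein prediction on an edited allele
#'
#' Maps the annotated exon boundaries onto the edited allele by unique
#' flanking-anchor matching (default 30-bp anchors taken from the wild-type
#' locus), removes introns whose both boundary anchors are found, then
#' locates the start codon via a short anchor immediately upstream of the
#' annotated ATG and translates to the first stop. This is the in-silico
#' analogue of RT-PCR plus cDNA sequencing across the splice junctions. When
#' the ATG context is gone (e.g. start codon excised) no ORF is called.
#'
#' @param allele edited allele (string or \code{\link{EditOutcome}}).
#' @param locus original locus DNA string.
#' @param model the \code{\link{GeneModel}}.
#' @param anchorLen exon-boundary anchor length (default 30 bp).
#' @param atgAnchorLen length of the upstream-of-ATG anchor (default 20 bp).
#' @return list(mrna, protein); protein is "" when no ORF is found.
#' @export
predictTranscript <- function(allele, locus, model, anchorLen = 30L,
                              atgAnchorLen = 20L) {
  if (is(allele, "EditOutcome")) allele <- allele@alleleSeq
  seq <- assertDNA(unname(locus)[1], "locus")
  ex <- model@exons
  n <- length(ex)
  txStartAnchor <- substr(seq, IRanges::start(ex)[1],
                          IRanges::start(ex)[1] + anchorLen - 1L)
  txEndAnchor <- substr(seq, IRanges::end(ex)[n] - anchorLen + 1L,
                        IRanges::end(ex)[n])
  s0 <- uniqueMatch(txStartAnchor, allele)
  e0 <- uniqueMatch(txEndAnchor, allele)
  if (s0 < 0L || e0 < 0L) stop("splice mapping ambiguous")
  if (s0 == 0L || e0 == 0L)
    return(list(mrna = "", protein = ""))
  txStart <- s0
  txEnd <- e0 + anchorLen - 1L
  pre <- substr(allele, txStart, txEnd)

  # remove each intron whose two boundary anchors map uniquely; an intron
  # with a destroyed splice site is retained (intron retention)
  for (i in seq_len(n - 1L)) {
    donorAnchor <- substr(seq, IRanges::end(ex)[i] - anchorLen + 1L,
                          IRanges::end(ex)[i])
    acceptorAnchor <- substr(seq, IRanges::start(ex)[i + 1L],
                             IRanges::start(ex)[i + 1L] + anchorLen - 1L)
    d <- uniqueMatch(donorAnchor, pre)
    a <- uniqueMatch(acceptorAnchor, pre)
    if (d < 0L || a < 0L) stop("splice mapping ambiguous")
    if (d == 0L || a == 0L) next
    dEnd <- d + anchorLen - 1L
    if (a <= dEnd) next
    pre <- paste0(substr(pre, 1L, dEnd), substr(pre, a, nchar(pre)))
  }
  mrna <- pre

  atgAnchor <- substr(seq, model@cdsStart - atgAnchorLen, model@cdsStart - 1L)
  m <- uniqueMatch(atgAnchor, mrna)
  if (m < 0L) stop("splice mapping ambiguous")
  if (m == 0L) return(list(mrna = mrna, protein = ""))
  cdsFrom <- m + atgAnchorLen
  if (substr(mrna, cdsFrom, cdsFrom + 2L) != "ATG")
    return(list(mrna = mrna, protein = ""))
  prot <- translateCDS(substr(mrna, cdsFrom, nchar(mrna)))
  list(mrna = mrna, protein = prot)
}

#' Classify a simulated outcome against the expected products
#'
#' KI: the predicted protein equals the tagged protein. WT: wild-type protein
#' with no insertion. Recuttable: both original target sites intact (reverse
#' insertions, and the unedited locus before editing). KO: donor absent (or
#' product destroyed) with the coding span disrupted.
#'
#' @param outcome an \code{\link{EditOutcome}} with transcript prediction run.
#' @param expected list from \code{\link{expectedProduct}}.
#' @return the outcome with \code{classification} (and intact-site dependent
#'   recuttable flag) set.
#' @export
classifyOutcome <- function(outcome, expected) {
  bothIntact <- nrow(outcome@intactSites) &&
    all(c("upstream", "downstream") %in% outcome@intactSites$site)
  cls <- if (nchar(outcome@protein) &&
             outcome@protein == expected$taggedProtein) {
    "KI"
  } else if (outcome@orientation == "unedited") {
    "WT"
  } else if (bothIntact) {
    "recuttable"
  } else if (nchar(outcome@protein) &&
             outcome@protein == expected$wtProtein) {
    "WT"      # e.g. intron-only excision religated without consequence
  } else {
    "KO"
  }
  outcome@classification <- cls
  outcome
}

#' Simulate the full outcome set for a design
#'
#' Runs the unedited, forward-insertion, reverse-insertion and KO-religation
#' paths for one donor design, with optional seeded junction INDELs, and
#' classifies each allele.
#'
#' @param locus locus DNA string.
#' @param model the \code{\link{GeneModel}}.
#' @param design the \code{\link{DonorDesign}}.
#' @param maxIndel junction INDEL bound in bp (default 0 = clean ligation).
#' @param seed RNG seed for the INDELs.
#' @param plasmid optional plasmid carrying the donor; by default the donor
#'   is padded with fixed 40-bp backbone stubs.
#' @return named list of \code{\link{EditOutcome}}: unedited, forward,
#'   reverse, ko.
#' @export
simulateOutcomes <- function(locus, model, design, maxIndel = 0L, seed = 1L,
                             plasmid = NULL) {
  seq <- assertDNA(unname(locus)[1], "locus")
  pair <- design@pair
  if (is.null(plasmid))
    plasmid <- paste0(BACKBONE_PAD_5, design@donorSeq, BACKBONE_PAD_3)
  arms <- cutLocus(seq, pair)
  fragment <- releaseDonor(plasmid, design)
  expect <- expectedProduct(seq, model, design@cassette,
                            design@insertionPoint)

  finish <- function(out) {
    out@intactSites <- detectIntactSites(out@alleleSeq, pair, seq)
    tp <- predictTranscript(out@alleleSeq, seq, model)
    out@mrna <- tp$mrna
    out@protein <- tp$protein
    classifyOutcome(out, expect)
  }

  unedited <- new("EditOutcome", alleleSeq = seq, orientation = "unedited",
                  junctions = data.frame(), intactSites = data.frame(),
                  mrna = "", protein = "", classification = "")
  fwd <- insertFragment(arms$left, arms$right, fragment, "forward")
  rev <- insertFragment(arms$left, arms$right, fragment, "reverse")
  ko <- religateKO(arms$left, arms$right)
  if (maxIndel > 0L) {
    fwd <- applyJunctionIndels(fwd, maxIndel, seed)
    rev <- applyJunctionIndels(rev, maxIndel, seed + 1L)
    ko <- applyJunctionIndels(ko, maxIndel, seed + 2L)
  }
  list(unedited = finish(unedited), forward = finish(fwd),
       reverse = finish(rev), ko = finish(ko))
}

# fixed plasmid backbone stubs used when no plasmid is supplied
BACKBONE_PAD_5 <- "TCGCGCGTTTCGGTGATGACGGTGAAAACCTCTGACACAT"
BACKBONE_PAD_3 <- "GCAGCTCCCGGAGACGGTCACAGCTTGTCTGTAAGCGGAT"

#' Outcome report as a plain list (JSON-ready)
#' @param outcomes named list from \code{\link{simulateOutcomes}}.
#' @param expected optional list from \code{\link{expectedProduct}} for a
#'   protein diff column.
#' @return list of per-outcome summaries.
#' @export
outcomeReport <- function(outcomes, expected = NULL) {
  lapply(outcomes, function(o) {
    rec <- list(orientation = o@orientation,
                classification = o@classification,
                allele_len = nchar(o@alleleSeq),
                intact_sites = nrow(o@intactSites),
                junctions = o@junctions,
                protein_len = nchar(o@protein))
    if (!is.null(expected))
      rec$protein_matches_wt <- identical(o@protein, expected$wtProtein)
    rec
  })
}
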