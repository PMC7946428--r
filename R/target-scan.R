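## SpCas9 target enumeration, non-coding filtering, scoring and pairing.
##
## Guide sites are plain data.frames (one row per site) with columns:
## protospacer, pam, strand, start, end (23-nt footprint, sense coordinates),
## cutPos, regionLabel, spliceDist, gcFrac, nOfftargets, onScore.
## cutPos encodes the blunt cut as "index of the last base kept on the left":
## SpCas9 cuts 3 bp 5' of the PAM, between protospacer positions 17|18.

emptySiteTable <- function() {
  data.frame(protospacer = character(0), pam = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             cutPos = integer(0), regionLabel = character(0),
             spliceDist = integer(0), gcFrac = numeric(0),
             nOfftargets = integer(0), onScore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Enumerate SpCas9 (NGG) target sites in a window
#'
#' Finds every 20-nt protospacer adjacent to an NGG PAM, on either strand,
#' whose full 23-nt footprint lies inside the window. Footprints containing N
#' are skipped. Sites are returned in deterministic order: footprint start,
#' then strand (+ before -).
#'
#' @param locus single DNA string (named or not).
#' @param window integer c(start, end), 1-based closed; default whole locus.
#' @return guide-site data.frame (possibly empty).
#' @export
scanPamSites <- function(locus, window = NULL) {
  seq <- assertDNA(unname(locus)[1], "locus")
  L <- nchar(seq)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L || window[1] > window[2])
    stop("window error: window outside locus bounds")
  if (window[2] - window[1] + 1L < 23L) return(emptySiteTable())

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  okFoot <- function(s) {
    if (!length(s)) return(list(s = integer(0), feet = character(0)))
    feet <- substring(seq, s, s + 22L)
    keep <- !grepl("N", feet, fixed = TRUE)
    list(s = s[keep], feet = feet[keep])
  }
  # plus strand: GG at footprint positions 22..23
  gg <- which(chars == "G")
  gg <- gg[gg < L]
  gg <- gg[chars[gg + 1L] == "G"]
  sP <- gg - 21L
  sP <- sP[sP >= window[1] & sP + 22L <= window[2]]
  plus <- okFoot(sP)
  # minus strand: CC at footprint positions 1..2 (NGG on the minus strand)
  cc <- which(chars == "C")
  cc <- cc[cc < L]
  cc <- cc[chars[cc + 1L] == "C"]
  sM <- cc[cc >= window[1] & cc + 22L <= window[2]]
  minus <- okFoot(sM)

  protoM <- if (length(minus$s))
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substring(minus$feet, 4L, 23L))))
  else character(0)
  pamM <- if (length(minus$s))
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substring(minus$feet, 1L, 3L))))
  else character(0)

  proto <- c(substring(plus$feet, 1L, 20L), protoM)
  if (!length(proto)) return(emptySiteTable())
  out <- data.frame(
    protospacer = proto,
    pam = c(substring(plus$feet, 21L, 23L), pamM),
    strand = rep(c("+", "-"), c(length(plus$s), length(minus$s))),
    start = c(plus$s, minus$s),
    end = c(plus$s, minus$s) + 22L,
    cutPos = c(plus$s + 16L, minus$s + 5L),
    regionLabel = NA_character_, spliceDist = NA_integer_,
    gcFrac = nchar(gsub("[^GC]", "", proto)) / 20,
    nOfftargets = NA_integer_, onScore = NA_real_,
    stringsAsFactors = FALSE)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Region label of a blunt-cut position (cut after base cutPos).
regionOfCut <- function(model, cutPos) {
  inAny <- function(ir, p) length(ir) && any(p >= IRanges::start(ir) & p <= IRanges::end(ir))
  geneStart <- min(IRanges::start(model@exons))
  geneEnd <- max(IRanges::end(model@exons))
  if (cutPos < geneStart || cutPos >= geneEnd) return("intergenic")
  if (inAny(introns(model), cutPos) && inAny(introns(model), cutPos + 1L))
    return("intron")
  if (inAny(utr5(model), cutPos) && inAny(utr5(model), cutPos + 1L))
    return("5'UTR")
  if (inAny(utr3(model), cutPos) && inAny(utr3(model), cutPos + 1L))
    return("3'UTR")
  if (cutPos >= model@cdsStart && cutPos < model@cdsEnd) return("CDS")
  "boundary"
}

# Distance (bp) from the blunt cut to the nearest interior splice junction.
spliceDistance <- function(model, cutPos) {
  ex <- model@exons
  if (length(ex) < 2L) return(NA_integer_)
  # junction boundaries expressed in the same "after base b" coordinate as cuts
  bounds <- c(IRanges::end(ex)[-length(ex)], IRanges::start(ex)[-1L] - 1L)
  as.integer(min(abs(cutPos - bounds)))
}

#' Keep guides cutting in permitted non-coding regions, away from splice sites
#'
#' Retains sites whose blunt cut lies in an allowed region (default 5'UTR and
#' intron) at least \code{minSpliceDist} bp from every interior splice
#' junction, and annotates \code{regionLabel} and \code{spliceDist} on the
#' survivors. Guides are kept well clear of splice junctions so that repair
#' INDELs around the cuts cannot disturb mRNA processing.
#'
#' @param sites guide-site data.frame from \code{\link{scanPamSites}}.
#' @param model the \code{\link{GeneModel}} for the same locus.
#' @param minSpliceDist minimum bp between cut and any splice junction
#'   (default 100).
#' @param allowedRegions regions a cut may fall in; "intergenic" may be added.
#' @return filtered, annotated guide-site data.frame.
#' @export
filterNoncoding <- function(sites, model, minSpliceDist = 100L,
                            allowedRegions = c("5'UTR", "intron")) {
  if (!nrow(sites)) return(sites)
  sites$regionLabel <- vapply(sites$cutPos, function(p) regionOfCut(model, p),
                              character(1))
  sd <- vapply(sites$cutPos, function(p) spliceDistance(model, p), integer(1))
  sites$spliceDist <- sd
  keep <- sites$regionLabel %in% allowedRegions &
    (is.na(sd) | sd >= minSpliceDist)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive Hamming off-target scan
#'
#' Reports every position on either strand of \code{genome} where a 20-mer
#' followed by an NGG PAM matches \code{protospacer} with at most
#' \code{maxMM} mismatches (mismatches counted over the 20-mer only; the GG
#' of the PAM must be exact). The on-target site is included, flagged by
#' \code{onTarget = mismatches == 0}. Matching uses
#' \code{Biostrings::matchPattern}; this is a full scan with no seed
#' weighting, i.e. conservative.
#'
#' @param protospacer 20-nt DNA string.
#' @param genome single DNA string or named character vector of sequences.
#' @param maxMM maximum mismatches (<= 4).
#' @return data.frame (seqname, pos = footprint start, strand, mismatches,
#'   onTarget).
#' @export
findOfftargets <- function(protospacer, genome, maxMM = 3L) {
  protospacer <- assertDNA(protospacer, "protospacer")
  stopifnot(nchar(protospacer) == 20L, maxMM >= 0L, maxMM <= 4L)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  hits <- list()
  scanStrand <- function(seqchar, strand, seqname) {
    subj <- Biostrings::DNAString(seqchar)
    L <- nchar(seqchar)
    m <- Biostrings::matchPattern(protospacer, subj, max.mismatch = maxMM,
                                  with.indels = FALSE)
    st <- Biostrings::start(m)
    for (p in st) {
      if (p + 22L > L) next
      pam <- substr(seqchar, p + 20L, p + 22L)
      if (substr(pam, 2L, 3L) != "GG") next
      mm <- sum(strsplit(substr(seqchar, p, p + 19L), "")[[1]] !=
                  strsplit(protospacer, "")[[1]])
      if (mm > maxMM) next
      pos <- if (strand == "+") p else L - (p + 22L) + 1L
      hits[[length(hits) + 1L]] <<- data.frame(
        seqname = seqname, pos = as.integer(pos), strand = strand,
        mismatches = as.integer(mm), onTarget = mm == 0L,
        stringsAsFactors = FALSE)
    }
  }
  for (nm in names(genome)) {
    seqchar <- assertDNA(unname(genome[nm]), nm)
    scanStrand(seqchar, "+", nm)
    scanStrand(revComp(seqchar), "-", nm)
  }
  if (!length(hits))
    return(data.frame(seqname = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      onTarget = logical(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$seqname, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transparent deterministic on-target guide score
#'
#' A simple, fully documented heuristic in [0, 1] (the scoring function is a
#' ranking device, not an efficiency prediction): start at 1.0; subtract 0.3
#' if GC fraction is outside [0.4, 0.7]; subtract 0.3 if the protospacer has
#' any homopolymer run of 5 or more; subtract 0.2 * min(1, number of
#' additional off-target hits with <= 3 mismatches); clamp to [0, 1].
#'
#' @param sites guide-site data.frame; if \code{nOfftargets} is NA the
#'   off-target term is 0 unless \code{extraOfftargets} is supplied.
#' @param extraOfftargets optional integer vector of additional (non
#'   on-target) hit counts, recycled.
#' @return the table with \code{onScore} (and \code{nOfftargets}) filled in.
#' @export
scoreGuide <- function(sites, extraOfftargets = NULL) {
  if (!nrow(sites)) return(sites)
  if (!is.null(extraOfftargets))
    sites$nOfftargets <- as.integer(rep_len(extraOfftargets, nrow(sites)))
  extra <- ifelse(is.na(sites$nOfftargets), 0L, sites$nOfftargets)
  score <- 1.0 -
    0.3 * (sites$gcFrac < 0.4 | sites$gcFrac > 0.7) -
    0.3 * vapply(sites$protospacer,
                 function(p) maxHomopolymer(p) >= 5L, logical(1)) -
    0.2 * pmin(1, extra)
  sites$onScore <- pmin(1, pmax(0, score))
  sites
}

# Sense-strand footprint string of a guide-site row.
footprintSense <- function(row) {
  if (row$strand == "+") paste0(row$protospacer, row$pam)
  else revComp(paste0(row$protospacer, row$pam))
}

# Would a clean forward insertion of the switch-and-flip donor reconstitute
# an intact target site at either ligation junction? This happens when the
# two protospacers share their PAM-proximal tail (probability ~ 4^-4 per
# pair) and such a knock-in allele would be re-cut, so the pair is unusable.
forwardJunctionSafe <- function(locus, upRow, dnRow) {
  seq <- unname(locus)[1]
  fco <- function(strand) if (strand == "+") 17L else 6L
  upFoot <- footprintSense(upRow)
  dnFoot <- footprintSense(dnRow)
  c1 <- upRow$cutPos; c2 <- dnRow$cutPos
  stub2 <- substr(revComp(dnFoot), 23L - fco(dnRow$strand) + 1L, 23L)
  stub1 <- substr(revComp(upFoot), 1L, 23L - fco(upRow$strand))
  leftJ <- paste0(substr(seq, max(1L, c1 - 21L), c1), stub2,
                  substr(seq, c1 + 1L, c1 + 22L))
  rightJ <- paste0(substr(seq, max(1L, c2 - 21L), c2), stub1,
                   substr(seq, c2 + 1L, c2 + 22L))
  pats <- c(upFoot, dnFoot, revComp(upFoot), revComp(dnFoot))
  for (j in c(leftJ, rightJ))
    for (p in pats)
      if (grepl(p, j, fixed = TRUE)) return(FALSE)
  TRUE
}

#' Pair upstream and downstream guides around the insertion point
#'
#' Forms all pairs (u, d) of filtered candidates such that the excised span
#' (u cut, d cut] strictly contains both the insertion point and the entire
#' coding stretch of the target exon (the exon holding the insertion point),
#' and the excised length does not exceed \code{maxExcised}. Pairs are ranked
#' by pair score = min(u, d on-target score) descending, then smaller excised
#' length, then leftmost upstream cut.
#'
#' @param candidates scored, filtered guide-site data.frame.
#' @param model the \code{\link{GeneModel}}.
#' @param insertionPoint locus coordinate after which the cassette goes.
#' @param maxExcised maximum cut-to-cut distance in bp.
#' @param topK number of pairs to return.
#' @param startClearance minimum bp between the upstream cut and the CDS
#'   start (default 25): repair INDELs at the upstream junction must not be
#'   able to reach the start-codon context (Kozak region), and ORF calling
#'   on edited alleles needs that context intact.
#' @param locus optional locus sequence; when supplied, pairs whose clean
#'   forward-insertion junctions would reconstitute an intact target site
#'   (guides sharing their PAM-proximal tail) are discarded, since such
#'   knock-in alleles would be re-cut.
#' @return list of \code{\link{GuidePair}} objects (length <= topK).
#' @export
pickGuidePairs <- function(candidates, model, insertionPoint,
                           maxExcised = 2000L, topK = 5L,
                           startClearance = 25L, locus = NULL) {
  if (!nrow(candidates)) stop("no pair: no candidate guides supplied")
  ex <- model@exons
  inExon <- which(insertionPoint >= IRanges::start(ex) &
                  insertionPoint <= IRanges::end(ex))
  if (!length(inExon))
    stop("no pair: insertion point is not inside an exon")
  target <- ex[inExon[1]]
  spanS <- max(IRanges::start(target), model@cdsStart)
  spanE <- min(IRanges::end(target), model@cdsEnd)

  # the start-codon clearance only binds when the start codon sits in the
  # target exon (N-terminal tagging); internal exons are unaffected
  upLimit <- if (model@cdsStart >= IRanges::start(target))
    min(spanS, model@cdsStart - startClearance) else spanS
  up <- candidates[candidates$cutPos < upLimit &
                   candidates$cutPos < insertionPoint, , drop = FALSE]
  dn <- candidates[candidates$cutPos >= spanE &
                   candidates$cutPos >= insertionPoint, , drop = FALSE]
  if (!nrow(up)) stop("no pair: no candidate cuts upstream of the coding span")
  if (!nrow(dn)) stop("no pair: no candidate cuts downstream of the coding span")

  pairs <- list()
  for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
    exc <- dn$cutPos[j] - up$cutPos[i]
    if (exc > maxExcised) next
    if (!is.null(locus) &&
        !forwardJunctionSafe(locus, up[i, , drop = FALSE],
                             dn[j, , drop = FALSE])) next
    pairs[[length(pairs) + 1L]] <- GuidePair(up[i, , drop = FALSE],
                                             dn[j, , drop = FALSE])
  }
  if (!length(pairs))
    stop("no pair: all pairs exceed maxExcised = ", maxExcised)
  score <- vapply(pairs, function(p) p@pairScore, numeric(1))
  exc <- vapply(pairs, function(p) p@excisedLen, integer(1))
  upcut <- vapply(pairs, function(p) cutUpstream(p), numeric(1))
  ord <- order(-score, exc, upcut)
  pairs[ord][seq_len(min(topK, length(pairs)))]
}

#' Tabulate guide sites or pairs for a delimited report
#' @param pairs list of GuidePair objects.
#' @return data.frame, one row per pair.
#' @export
pairReport <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) data.frame(
    upCut = cutUpstream(p), upStrand = p@upstream$strand,
    upProtospacer = p@upstream$protospacer, upPam = p@upstream$pam,
    dnCut = cutDownstream(p), dnStrand = p@downstream$strand,
    dnProtospacer = p@downstream$protospacer, dnPam = p@downstream$pam,
    excisedLen = p@excisedLen, pairScore = p@pairScore,
    stringsAsFactors = FALSE)))
}
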