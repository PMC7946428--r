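## Deterministic synthetic-data generators.
##
## Every generator takes one integer seed and never consumes global RNG
## state, so all tests are bit-reproducible without downloads. The toy locus
## emulates the shape of the targeted loci in two-guide non-coding knock-in
## designs: a multi-exon gene whose first exon carries a 5'UTR and the
## signal-peptide-bearing start of the CDS, with guide sites planted in the
## 5'UTR and the first intron at configurable distances from the splice
## junctions.

#' Generate a synthetic multi-exon locus with planted SpCas9 sites
#'
#' Builds a random locus containing one plus-strand gene (flank, exon 1 =
#' 5'UTR + first CDS stretch, intron(s), further exons, 3'UTR, flank) and
#' stamps 23-nt protospacer+PAM target sites at the requested cut positions.
#' Each planted footprint is verified to occur exactly once genome-wide
#' (both strands, 0 mismatches); the locus is resampled if a collision
#' occurs. The truth record carries the planted cut coordinates and the
#' wild-type protein.
#'
#' @param seed integer seed driving all randomness.
#' @param utr5Len,utr3Len UTR lengths (bp).
#' @param cdsExonLens CDS bp per exon (each divisible by 3; the final 3 bp
#'   of the last element are replaced by the stop codon).
#' @param intronLens intron lengths, one fewer than exons.
#' @param flank intergenic padding on each side.
#' @param signalPeptideAA signal-peptide length in codons (for truth record).
#' @param plantedSites data.frame (region, offset, strand): region one of
#'   "5'UTR" or "intron<i>", offset = cut position in bp from the region
#'   start, strand the protospacer strand. Default: one 5'UTR site (+) and
#'   one intron-1 site (-), both >= 100 bp from every splice junction.
#' @return list(locus, model, sites, truth): named locus string, GeneModel,
#'   planted-site table in \code{\link{scanPamSites}} schema, and truth list.
#' @export
makeToyLocus <- function(seed = 1L, utr5Len = 220L, utr3Len = 120L,
                         cdsExonLens = c(90L, 120L), intronLens = 400L,
                         flank = 150L, signalPeptideAA = 4L,
                         plantedSites = data.frame(
                           region = c("5'UTR", "intron1"),
                           offset = c(110L, 250L),
                           strand = c("+", "-"),
                           stringsAsFactors = FALSE)) {
  stopifnot(length(intronLens) == length(cdsExonLens) - 1L,
            all(cdsExonLens %% 3L == 0L), utr5Len >= 40L,
            3L * signalPeptideAA < cdsExonLens[1])
  withSeed(seed, {
    for (attempt in 1:50) {
      fix <- buildToyLocusOnce(utr5Len, utr3Len, cdsExonLens, intronLens,
                               flank, signalPeptideAA, plantedSites)
      if (!is.null(fix)) return(fix)
    }
    stop("infeasible locus spec: could not place unique planted sites")
  })
}

buildToyLocusOnce <- function(utr5Len, utr3Len, cdsExonLens, intronLens,
                              flank, signalPeptideAA, plantedSites) {
  nEx <- length(cdsExonLens)
  cdsTotal <- sum(cdsExonLens)
  coding <- paste0("ATG", randomCodons(cdsTotal / 3L - 2L), "TAA")
  stopifnot(nchar(coding) == cdsTotal)

  exonSeqs <- character(nEx)
  ofs <- 0L
  for (i in seq_len(nEx)) {
    cdsPart <- substr(coding, ofs + 1L, ofs + cdsExonLens[i])
    ofs <- ofs + cdsExonLens[i]
    exonSeqs[i] <- cdsPart
  }
  exonSeqs[1] <- paste0(randomDNA(utr5Len), exonSeqs[1])
  exonSeqs[nEx] <- paste0(exonSeqs[nEx], randomDNA(utr3Len))

  pieces <- character(0)
  starts <- integer(nEx)
  pos <- flank
  for (i in seq_len(nEx)) {
    starts[i] <- pos + 1L
    pieces <- c(pieces, exonSeqs[i])
    pos <- pos + nchar(exonSeqs[i])
    if (i < nEx) {
      pieces <- c(pieces, randomDNA(intronLens[i]))
      pos <- pos + intronLens[i]
    }
  }
  locusSeq <- paste0(randomDNA(flank), paste(pieces, collapse = ""),
                     randomDNA(flank))
  exons <- IRanges::IRanges(starts, starts + nchar(exonSeqs) - 1L)
  cdsStart <- starts[1] + utr5Len
  cdsEnd <- starts[nEx] + cdsExonLens[nEx] - 1L
  model <- GeneModel("toygene", "toychr", "+", exons, cdsStart, cdsEnd,
                     origin = list(start = 1L, end = nchar(locusSeq),
                                   width = nchar(locusSeq)))

  # stamp planted sites at their requested cut positions
  introns_ <- introns(model)
  siteRows <- list()
  for (k in seq_len(nrow(plantedSites))) {
    reg <- plantedSites$region[k]
    cutPos <- if (reg == "5'UTR") {
      starts[1] - 1L + as.integer(plantedSites$offset[k])
    } else if (grepl("^intron", reg)) {
      i <- as.integer(sub("intron", "", reg))
      IRanges::start(introns_)[i] - 1L + as.integer(plantedSites$offset[k])
    } else stop("infeasible locus spec: unknown planted region ", reg)
    strand <- plantedSites$strand[k]
    s <- if (strand == "+") cutPos - 16L else cutPos - 5L
    proto <- randomDNA(20L)
    foot <- if (strand == "+") paste0(proto, sample(c("A", "C", "G", "T"), 1),
                                      "GG")
            else paste0("CC", sample(c("A", "C", "G", "T"), 1),
                        revComp(proto))
    substr(locusSeq, s, s + 22L) <- foot
    siteRows[[k]] <- list(s = s, strand = strand, cutPos = cutPos,
                          region = reg)
  }
  # re-extract footprints (stamps could in principle overlap) and verify
  # genome-wide uniqueness of each protospacer+PAM
  sites <- scanPamSites(locusSeq)
  planted <- list()
  for (k in seq_along(siteRows)) {
    r <- siteRows[[k]]
    hit <- sites[sites$start == r$s & sites$strand == r$strand, , drop = FALSE]
    if (nrow(hit) != 1L) return(NULL)
    ot <- findOfftargets(hit$protospacer, locusSeq, maxMM = 0L)
    if (nrow(ot) != 1L) return(NULL)
    hit$regionLabel <- sub("[0-9]+$", "", r$region)
    hit$spliceDist <- spliceDistance(model, hit$cutPos)
    planted[[k]] <- hit
  }
  planted <- do.call(rbind, planted)
  if (any(planted$cutPos != vapply(siteRows, `[[`, integer(1), "cutPos")))
    return(NULL)
  # reroll pairs whose forward-insertion junctions would reconstitute a
  # target site (guides sharing their PAM-proximal tail)
  if (nrow(planted) >= 2L &&
      !forwardJunctionSafe(locusSeq, planted[1, , drop = FALSE],
                           planted[nrow(planted), , drop = FALSE]))
    return(NULL)

  locus <- setNames(locusSeq, "toychr")
  wt <- spliceWildType(locusSeq, model)
  truth <- list(
    seedLocusLen = nchar(locusSeq),
    cutUpstream = planted$cutPos[1], cutDownstream = planted$cutPos[2],
    wtProtein = translateCDS(substr(wt$mrna, wt$cdsOffset, nchar(wt$mrna))),
    cdsStart = cdsStart, cdsEnd = cdsEnd,
    signalPeptideAA = signalPeptideAA,
    utr5Len = utr5Len, exonStarts = starts)
  list(locus = locus, model = model, sites = planted, truth = truth)
}

#' Write a toy locus as genome FASTA + GFF3
#'
#' Emits the files \code{genome.fa} and \code{genes.gff3} that
#' \code{\link{loadLocus}} consumes. With \code{strand = "-"} the chromosome
#' is written reverse-complemented and all features flipped to the minus
#' strand, which must load back to the identical sense-strand model (the
#' strand-invariance property).
#'
#' @param fix list from \code{\link{makeToyLocus}}.
#' @param dir output directory (created if needed).
#' @param strand strand to place the gene on ("+" or "-").
#' @return named character vector with the two file paths.
#' @export
writeToyLocus <- function(fix, dir, strand = "+") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  locusSeq <- unname(fix$locus)
  model <- fix$model
  L <- nchar(locusSeq)
  ex <- model@exons
  cds <- IRanges::IRanges(model@cdsStart, model@cdsEnd)
  if (strand == "-") {
    locusSeq <- revComp(locusSeq)
    flip <- function(ir) IRanges::IRanges(L - IRanges::end(ir) + 1L,
                                          L - IRanges::start(ir) + 1L)
    ex <- flip(ex)
    ex <- ex[order(IRanges::start(ex))]
    cds <- flip(cds)
  }
  fa <- file.path(dir, "genome.fa")
  writeFasta(setNames(locusSeq, "toychr"), fa)

  geneSpan <- c(min(IRanges::start(ex)), max(IRanges::end(ex)))
  cdsParts <- IRanges::intersect(cds, ex)
  allRanges <- c(IRanges::IRanges(geneSpan[1], geneSpan[2]),
                 IRanges::IRanges(geneSpan[1], geneSpan[2]),
                 ex, cdsParts)
  nEx <- length(ex); nCds <- length(cdsParts)
  gr <- GenomicRanges::GRanges("toychr", allRanges, strand = strand)
  S4Vectors::mcols(gr)$type <- c("gene", "mRNA", rep("exon", nEx),
                                 rep("CDS", nCds))
  S4Vectors::mcols(gr)$ID <- c("toygene", "toygene.t1",
                               paste0("toygene.t1.exon", seq_len(nEx)),
                               paste0("toygene.t1.cds", seq_len(nCds)))
  S4Vectors::mcols(gr)$Name <- S4Vectors::mcols(gr)$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    c(list(character(0)), list("toygene"),
      rep(list("toygene.t1"), nEx + nCds)))
  txOrder <- if (strand == "+") seq_len(nCds) else rev(seq_len(nCds))
  cum <- c(0L, cumsum(IRanges::width(cdsParts)[txOrder]))[seq_len(nCds)]
  phase <- integer(nCds); phase[txOrder] <- (3L - cum %% 3L) %% 3L
  S4Vectors::mcols(gr)$phase <- c(rep(NA_integer_, 2L + nEx), phase)
  gff <- file.path(dir, "genes.gff3")
  rtracklayer::export(gr, gff, format = "gff3")
  c(genome = fa, gff = gff)
}

#' Generate a synthetic normalized FRAP trace
#'
#' Two pre-bleach points at 1.0 followed by \code{nPost} post-bleach points
#' from the one-phase-decay model
#' f(t') = (1 - immobileFrac) * (1 - exp(-t'/tau)), plus seeded Gaussian
#' noise. The default 1-minute spacing matches typical z-stack acquisition
#' every 60 s.
#'
#' @param tau recovery time constant (minutes, > 0).
#' @param immobileFrac immobile fraction in [0, 1].
#' @param noiseSd Gaussian noise SD (0 = noiseless).
#' @param nPost number of post-bleach points (>= 4).
#' @param dt grid spacing in minutes.
#' @param seed RNG seed.
#' @return a \code{\link{FrapTrace}}.
#' @export
makeFrapTrace <- function(tau, immobileFrac, noiseSd = 0, nPost = 10L,
                          dt = 1.0, seed = 1L) {
  stopifnot(tau > 0, immobileFrac >= 0, immobileFrac <= 1, nPost >= 4L)
  withSeed(seed, {
    tPre <- c(0, dt)
    tPost <- seq(2 * dt, by = dt, length.out = nPost)
    tp <- tPost - tPost[1]
    f <- c(rep(1, 2), (1 - immobileFrac) * (1 - exp(-tp / tau)))
    if (noiseSd > 0) f <- f + rnorm(length(f), sd = noiseSd)
    FrapTrace(c(tPre, tPost), f, bleachIndex = 3L)
  })
}

#' Generate a synthetic KI/WT/KO cell-count table
#'
#' Seeded multinomial cell classes with class-specific marker intensities.
#' All cells are mCherry+, KI cells are GFP+, and marker intensity is drawn
#' from a class Gaussian (clamped at 0): WT-like levels for KI and WT cells,
#' near background for KO cells. Ground-truth fractions are recorded.
#'
#' @param n number of cells.
#' @param pKi,pKo class probabilities (pKi + pKo <= 1; WT takes the rest).
#' @param intensityParams list with wtMean, wtSd, koMean, koSd.
#' @param seed RNG seed.
#' @return list(cells = data.frame(cellId, mcherryPos, gfpPos,
#'   markerIntensity), truth = list(...)).
#' @export
makeCellTable <- function(n, pKi, pKo,
                          intensityParams = list(wtMean = 300, wtSd = 60,
                                                 koMean = 10, koSd = 5),
                          seed = 1L) {
  stopifnot(pKi >= 0, pKo >= 0, pKi + pKo <= 1)
  withSeed(seed, {
    cls <- sample(c("KI", "KO", "WT"), n, replace = TRUE,
                  prob = c(pKi, pKo, 1 - pKi - pKo))
    p <- intensityParams
    intensity <- ifelse(cls == "KO",
                        rnorm(n, p$koMean, p$koSd),
                        rnorm(n, p$wtMean, p$wtSd))
    cells <- data.frame(
      cellId = sprintf("cell%04d", seq_len(n)),
      mcherryPos = TRUE,
      gfpPos = cls == "KI",
      markerIntensity = pmax(intensity, 0),
      stringsAsFactors = FALSE)
    truth <- list(classes = cls, pKi = pKi, pKo = pKo,
                  fractions = table(factor(cls, c("KI", "WT", "KO"))) / n)
    list(cells = cells, truth = truth)
  })
}

#' One-call toy design: locus, filtered pair, cassette, donor
#'
#' Convenience wrapper used throughout the tests and examples: generates a
#' toy locus, scores the planted sites, pairs them, resolves the insertion
#' point after the signal peptide and builds the donor.
#'
#' @param seed locus seed.
#' @param cassette optional \code{\link{TagCassette}}; default a 30-bp
#'   in-frame tag inserted after the signal peptide.
#' @param ... passed to \code{\link{makeToyLocus}}.
#' @return list(locus, model, sites, truth, pair, cassette, insertionPoint,
#'   design).
#' @export
makeToyDesign <- function(seed = 1L, cassette = NULL, ...) {
  fix <- makeToyLocus(seed = seed, ...)
  if (is.null(cassette))
    cassette <- TagCassette("miniTag",
                            tagSeq = "TACGGCAAGCTGACCCTGAAGTTCATC",
                            linker5 = "GGA", linker3 = "",
                            insertionMode = "after_signal_peptide",
                            signalPeptideAA = fix$truth$signalPeptideAA)
  sites <- scoreGuide(filterNoncoding(fix$sites, fix$model))
  ip <- resolveInsertionPoint(fix$model, cassette)
  pairs <- pickGuidePairs(sites, fix$model, ip, locus = fix$locus)
  design <- buildDonor(fix$locus, pairs[[1]], cassette, ip)
  c(fix, list(pair = pairs[[1]], cassette = cassette, insertionPoint = ip,
              design = design))
}

#' Synthetic template fragments for the four-fragment guide-vector assembly
#'
#' Builds plausible amplicons for an in-silico assembly check: each PCR
#' fragment is its forward primer, a random interior, and the reverse
#' complement of its reverse primer; the vector fragment carries the two
#' template-defined junction sequences at its ends. Assembling the four
#' fragments yields one circular sequence with both guide cassettes in
#' tandem.
#'
#' @param set a \code{\link{GuideCloningSet}}.
#' @param seed RNG seed for the interiors.
#' @return character vector of 4 fragments in assembly order
#'   (vector, frag2, frag3, frag4).
#' @export
makeGuideVectorFragments <- function(set, seed = 1L) {
  withSeed(seed, {
    p <- setNames(set@primers$seq, set@primers$name)
    amplicon <- function(fwd, rev, interiorLen = 120L)
      paste0(fwd, randomDNA(interiorLen), revComp(toupper(rev)))
    frag2 <- amplicon(p["common_F"], p["frag2_R"])
    frag3 <- amplicon(p["frag3_F"], p["frag3_R"])
    frag4 <- amplicon(p["frag4_F"], p["common_R"])
    # vector fragment: starts where common_R homology ends, ends where
    # common_F begins (PciI/Acc65I-style linearisation)
    vecStart <- revComp(toupper(p["common_R"]))
    vecEnd <- toupper(substr(p["common_F"], 1L, 30L))
    vector <- paste0(vecStart, randomDNA(200L), vecEnd)
    c(vector = vector, frag2 = frag2, frag3 = frag3, frag4 = frag4)
  })
}
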