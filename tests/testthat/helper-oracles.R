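# Independent oracles and small shared fixtures.
# These deliberately use a different code path from the package internals.

# Naive position-by-position Hamming scan for protospacer+NGG hits.
naiveOfftargetScan <- function(protospacer, genomeStr, maxMM) {
  protoRaw <- charToRaw(protospacer)
  scan1 <- function(s, strand) {
    L <- nchar(s)
    if (L < 23L) return(NULL)
    starts <- seq_len(L - 22L)
    subs <- substring(s, starts, starts + 19L)
    pams <- substring(s, starts + 21L, starts + 22L)
    keep <- pams == "GG"
    res <- lapply(which(keep), function(i) {
      mm <- sum(charToRaw(subs[i]) != protoRaw)
      if (mm > maxMM) return(NULL)
      pos <- if (strand == "+") starts[i] else L - (starts[i] + 22L) + 1L
      data.frame(pos = pos, strand = strand, mismatches = mm)
    })
    do.call(rbind, res)
  }
  rcStr <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genomeStr)))
  out <- rbind(scan1(genomeStr, "+"), scan1(rcStr, "-"))
  if (is.null(out)) return(data.frame(pos = integer(0), strand = character(0),
                                      mismatches = integer(0)))
  out[order(out$pos, out$strand), , drop = FALSE]
}

# Brute-force regex scan for all NGG / CCN footprints on a sense string.
regexPamScan <- function(s) {
  L <- nchar(s)
  plus <- integer(0); minus <- integer(0)
  for (i in seq_len(max(L - 22L, 0L))) {
    w <- substr(s, i, i + 22L)
    if (grepl("N", w, fixed = TRUE)) next
    if (substr(w, 22L, 23L) == "GG") plus <- c(plus, i)
    if (substr(w, 1L, 2L) == "CC") minus <- c(minus, i)
  }
  list(plus = plus, minus = minus)
}

# A short in-frame tag cassette used across tests (30 bp with linker).
standardCassette <- function(spAA = 4L) {
  TagCassette("miniTag", tagSeq = "TACGGCAAGCTGACCCTGAAGTTCATC",
              linker5 = "GGA", linker3 = "",
              insertionMode = "after_signal_peptide",
              signalPeptideAA = spAA)
}

# Random DNA string helper independent of package internals.
rndSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

# Randomized-but-deterministic toy design: geometry varies with the seed so
# property tests cover many locus shapes, guide strands and tag offsets.
randomToyDesign <- function(seed) {
  seed <- as.integer(seed)
  utr5 <- 150L + (seed * 37L) %% 120L
  intron <- 300L + (seed * 53L) %% 220L
  utrOff <- 40L + (seed * 17L) %% (utr5 - 70L)
  intronOff <- 100L + (seed * 29L) %% (intron - 200L)
  strands <- list(c("+", "-"), c("-", "+"), c("+", "+"),
                  c("-", "-"))[[1L + seed %% 4L]]
  spAA <- 2L + seed %% 12L
  cassette <- TagCassette("miniTag", tagSeq = "TACGGCAAGCTGACCCTGAAGTTCATC",
                          linker5 = "GGA", linker3 = "",
                          insertionMode = "after_signal_peptide",
                          signalPeptideAA = spAA)
  makeToyDesign(
    seed = seed, cassette = cassette,
    utr5Len = utr5, intronLens = intron,
    signalPeptideAA = spAA,
    plantedSites = data.frame(
      region = c("5'UTR", "intron1"),
      offset = c(utrOff, intronOff),
      strand = strands, stringsAsFactors = FALSE))
}
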