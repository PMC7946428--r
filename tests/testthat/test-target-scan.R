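test_that("scanPamSites enumerates NGG footprints with the -3 blunt-cut rule", {
  # too short for any 23-nt footprint
  expect_equal(nrow(scanPamSites("ACGTACGGTT")), 0L)

  # a single forced plus-strand site: protospacer + CGG
  proto <- "GACGTACGTACGTACGTACG"
  one <- scanPamSites(paste0(proto, "CGG"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$protospacer, proto)
  expect_equal(one$pam, "CGG")
  expect_equal(one$strand, "+")
  expect_equal(one$cutPos, 17L)

  # full scan equals a brute-force regex scan of both strands, in order
  set.seed(11)
  for (rep in 1:5) {
    s <- rndSeq(300)
    got <- scanPamSites(s)
    oracle <- regexPamScan(s)
    expect_equal(got$start[got$strand == "+"], oracle$plus)
    expect_equal(got$start[got$strand == "-"], oracle$minus)
    expect_true(!is.unsorted(got$start))
    # re-extract each footprint and confirm protospacer/PAM/cut geometry
    for (i in seq_len(nrow(got))) {
      foot <- substr(s, got$start[i], got$end[i])
      if (got$strand[i] == "+") {
        expect_equal(paste0(got$protospacer[i], got$pam[i]), foot)
        expect_equal(got$cutPos[i], got$start[i] + 16L)
      } else {
        expect_equal(paste0(got$protospacer[i], got$pam[i]), revComp(foot))
        expect_equal(got$cutPos[i], got$start[i] + 5L)
      }
      expect_match(got$pam[i], "^[ACGT]GG$")
    }
  }

  expect_error(scanPamSites("ACGT", window = c(0, 4)), "window")
})

test_that("filterNoncoding keeps 5'UTR/intron cuts far from splice junctions", {
  planted <- data.frame(
    region = c("5'UTR", "5'UTR", "intron1", "intron1", "intron1"),
    offset = c(40L, 150L, 40L, 250L, 340L),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  fix <- makeToyLocus(seed = 13, plantedSites = planted)
  kept <- filterNoncoding(fix$sites, fix$model, minSpliceDist = 100)

  # manual distance table: exon1 = 220 UTR + 90 CDS (ends 310 into the gene),
  # intron1 = 400 bp. UTR cuts at 40/150 sit 270/160 bp from the junction
  # (kept); intron cuts at 40/250/340 sit 40/150/60 bp away (only 250 kept).
  expect_equal(nrow(kept), 3L)
  expect_equal(sort(kept$spliceDist), c(150L, 160L, 270L))
  expect_setequal(kept$regionLabel, c("5'UTR", "intron"))
  utrKept <- kept[kept$regionLabel == "5'UTR", ]
  expect_equal(sort(utrKept$spliceDist), c(160L, 270L))

  # a 40-bp-in intron cut is dropped
  expect_false(any(kept$spliceDist < 100))
})

test_that("filterNoncoding never returns a cut inside the CDS", {
  for (seed in c(3, 17)) {
    fix <- makeToyLocus(seed = seed)
    all <- scanPamSites(fix$locus)
    kept <- filterNoncoding(all, fix$model)
    if (!nrow(kept)) next
    # CDS intervals are the exonic pieces of the CDS span, not the span
    # itself (introns between coding exons are legitimate cut zones)
    cdsPieces <- IRanges::intersect(
      IRanges::IRanges(fix$model@cdsStart, fix$model@cdsEnd),
      exons(fix$model))
    inCds <- IRanges::overlapsAny(
      IRanges::IRanges(kept$cutPos, kept$cutPos), cdsPieces)
    expect_false(any(inCds))
    expect_true(all(kept$regionLabel %in% c("5'UTR", "intron")))
  }
})

test_that("findOfftargets matches constructed decoys at each mismatch radius", {
  set.seed(5)
  proto <- rndSeq(20)
  decoy <- proto
  substr(decoy, 3, 3) <- if (substr(decoy, 3, 3) == "A") "C" else "A"
  substr(decoy, 15, 15) <- if (substr(decoy, 15, 15) == "G") "T" else "G"
  genome <- paste0(rndSeq(200), proto, "AGG", rndSeq(150), decoy, "TGG",
                   rndSeq(100))

  exact <- findOfftargets(proto, genome, maxMM = 0)
  expect_equal(nrow(exact), 1L)
  expect_true(exact$onTarget)

  expect_equal(nrow(findOfftargets(proto, genome, maxMM = 1)), 1L)
  two <- findOfftargets(proto, genome, maxMM = 2)
  expect_equal(nrow(two), 2L)
  expect_equal(sum(two$onTarget), 1L)
  expect_equal(sort(two$mismatches), c(0L, 2L))
})

test_that("findOfftargets equals the naive Hamming oracle on random genomes", {
  set.seed(99)
  for (rep in 1:4) {
    genome <- rndSeq(4000)
    # use a protospacer actually present so the on-target hit is exercised
    sites <- scanPamSites(genome)
    proto <- sites$protospacer[sample(nrow(sites), 1)]
    got <- findOfftargets(proto, genome, maxMM = 3)
    oracle <- naiveOfftargetScan(proto, genome, 3)
    expect_equal(got$pos, oracle$pos)
    expect_equal(got$strand, oracle$strand)
    expect_equal(got$mismatches, oracle$mismatches)
  }
})

test_that("guide score applies the documented penalties", {
  mkSite <- function(proto, nOff = 0L) {
    s <- scanPamSites(paste0(proto, "CGG"))
    scoreGuide(s, extraOfftargets = nOff)
  }
  # homopolymer run of 5 G's, GC in range -> 0.7
  expect_equal(mkSite("GGGGGACGTACGTACGTACG")$onScore, 0.7)
  # GC = 0.5, no homopolymer, no extra off-targets -> 1.0
  expect_equal(mkSite("GACGTACGTACGTACGTACG")$onScore, 1.0)
  # GC = 0.2 with one extra 3-mm off-target -> 1 - 0.3 - 0.2 = 0.5
  expect_equal(mkSite("GATATATATTATATATATAC", nOff = 1L)$onScore, 0.5)
  # penalties clamp at 0
  expect_gte(mkSite("GGGGGAAAAATTTTTAAAAT", nOff = 5L)$onScore, 0)
})

test_that("guide pairing enforces the excision contract and ranking", {
  fix <- makeToyLocus(seed = 3)
  sites <- scoreGuide(filterNoncoding(fix$sites, fix$model))
  cassette <- standardCassette(fix$truth$signalPeptideAA)
  ip <- resolveInsertionPoint(fix$model, cassette)

  # exactly one upstream and one downstream survivor -> one pair
  pairs <- pickGuidePairs(sites, fix$model, ip)
  expect_length(pairs, 1L)
  p <- pairs[[1]]
  expect_lt(cutUpstream(p), fix$model@cdsStart)
  expect_gt(cutDownstream(p), ip)
  # the coding stretch of the target exon lies strictly between the cuts
  expect_lt(cutUpstream(p), fix$model@cdsStart)
  expect_gte(cutDownstream(p), IRanges::end(exons(fix$model))[1])

  # ranking: equal scores -> smaller excision first; then leftmost cut
  base <- sites[rep(1, 4), ]
  base$onScore <- 1
  base$cutPos <- c(100L, 300L, 900L, 1300L)   # 2 upstream, 2 downstream
  base$start <- base$cutPos - 16L; base$end <- base$start + 22L
  model2 <- GeneModel("g", "c", "+",
                      IRanges::IRanges(c(400, 1500), c(800, 1900)),
                      cdsStart = 500, cdsEnd = 1600)
  got <- pickGuidePairs(base, model2, insertionPoint = 503L,
                        maxExcised = 5000L, topK = 10L)
  key <- vapply(got, function(p) c(p@excisedLen, cutUpstream(p)), numeric(2))
  expect_equal(key[1, ], sort(key[1, ]))          # excision ascending
  expect_equal(key[1, ], c(600, 800, 1000, 1200)) # hand-ranked order
  expect_length(got, 4L)
  # pruning by maxExcised drops the two widest pairs
  got2 <- pickGuidePairs(base, model2, 503L, maxExcised = 800L, topK = 10L)
  expect_length(got2, 2L)
  expect_error(pickGuidePairs(base, model2, 503L, maxExcised = 10L),
               "no pair")
})
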