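test_that("cutLocus splits at the blunt cuts and conserves the sequence", {
  x <- makeToyDesign(seed = 3)
  arms <- cutLocus(x$locus, x$pair)
  c1 <- cutUpstream(x$pair); c2 <- cutDownstream(x$pair)
  L <- nchar(unname(x$locus))

  expect_equal(nchar(arms$left), c1)
  expect_equal(nchar(arms$excised), c2 - c1)
  expect_equal(nchar(arms$right), L - c2)
  expect_equal(paste0(arms$left, arms$excised, arms$right), unname(x$locus))

  # the cut sits 3 bp 5' of the PAM on the protospacer strand
  up <- x$pair@upstream
  if (up$strand == "+") expect_equal(up$cutPos, up$start + 16L)
  else expect_equal(up$cutPos, up$start + 5L)
})

test_that("donor release cuts inside the flipped end sites, keeping stubs", {
  x <- makeToyDesign(seed = 3)
  pad5 <- "TTGACGCGCAAGCTTGCATGCCTGCA"
  pad3 <- "GGTACCGAGCTCGAATTCACTGGCCG"
  plasmid <- paste0(pad5, donorSeq(x$design), pad3)
  frag <- releaseDonor(plasmid, x$design)

  # manual cut-position arithmetic: each flipped site is cut 3 bp from its
  # PAM, leaving a (23 - cutoff) stub at the 5' end and a cutoff stub at the
  # 3' end, where cutoff is 17 for a plus-strand genomic guide and 6 for a
  # minus-strand one (mirrored by the flip)
  # a plus-strand genomic guide leaves 17 nt of its footprint on the
  # excised/fragment side (6 nt stay genomic); a minus-strand guide the
  # mirror image -- so the backbone loses (23 - kept) per end
  kept2 <- if (x$pair@downstream$strand == "+") 17L else 6L
  kept1 <- if (x$pair@upstream$strand == "+") 6L else 17L
  expect_equal(nchar(frag),
               nchar(donorSeq(x$design)) - (23L - kept2) - (23L - kept1))

  # the complete cassette is inside the fragment
  expect_true(grepl(cassetteSeq(x$cassette), frag, fixed = TRUE))

  # plasmid missing one end site is ambiguous
  broken <- paste0(pad5, substr(donorSeq(x$design), 10, nchar(donorSeq(x$design))),
                   pad3)
  expect_error(releaseDonor(broken, x$design), "donor sites ambiguous")
})

test_that("ligation is blunt and orientation bookkeeping is exact", {
  x <- makeToyDesign(seed = 4)
  arms <- cutLocus(x$locus, x$pair)
  frag <- releaseDonor(paste0("GATCGATTACA", donorSeq(x$design), "TGTAATCGATC"),
                       x$design)

  fwd <- insertFragment(arms$left, arms$right, frag, "forward")
  rev <- insertFragment(arms$left, arms$right, frag, "reverse")
  expect_equal(nchar(alleleSeq(fwd)),
               nchar(arms$left) + nchar(frag) + nchar(arms$right))
  expect_equal(fwd@junctions$pos,
               c(nchar(arms$left), nchar(arms$left) + nchar(frag)))
  # reverse of the reverse-inserted block restores the fragment
  inner <- substr(alleleSeq(rev), nchar(arms$left) + 1,
                  nchar(arms$left) + nchar(frag))
  expect_equal(revComp(inner), frag)
})

test_that("intact-site detection captures the re-cut asymmetry", {
  x <- makeToyDesign(seed = 5)
  out <- simulateOutcomes(x$locus, x$model, x$design)

  expect_equal(nrow(out$unedited@intactSites), 2L)
  expect_equal(nrow(out$forward@intactSites), 0L)
  # the method's defining claim: reverse insertion regenerates both sites
  rev <- out$reverse@intactSites
  expect_equal(nrow(rev), 2L)
  expect_setequal(rev$site, c("upstream", "downstream"))
})

test_that("religation yields a KO allele when coding sequence is excised", {
  x <- makeToyDesign(seed = 6)
  out <- simulateOutcomes(x$locus, x$model, x$design)
  ko <- out$ko
  expect_equal(ko@orientation, "none_ko")
  expect_equal(classification(ko), "KO")
  expect_equal(nchar(alleleSeq(ko)),
               nchar(unname(x$locus)) - x$pair@excisedLen)
  expect_equal(ko@protein, "")
})

test_that("intron-only excision religates back to a wild-type product", {
  # hostile fixture: both guides inside intron 1, nothing coding removed
  planted <- data.frame(region = c("intron1", "intron1"),
                        offset = c(120L, 280L), strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  fix <- makeToyLocus(seed = 31, plantedSites = planted)
  pair <- GuidePair(fix$sites[1, ], fix$sites[2, ])
  arms <- cutLocus(fix$locus, pair)
  out <- religateKO(arms$left, arms$right)
  out@intactSites <- detectIntactSites(out@alleleSeq, pair, fix$locus)
  tp <- predictTranscript(out@alleleSeq, fix$locus, fix$model)
  out@protein <- tp$protein
  wt <- spliceWildType(fix$locus, fix$model)
  expected <- list(wtProtein = fix$truth$wtProtein,
                   taggedProtein = "impossible")
  out <- classifyOutcome(out, expected)
  expect_equal(classification(out), "WT")   # flagged as not-KO
  expect_equal(out@protein, fix$truth$wtProtein)
})

test_that("junction INDELs are seeded, bounded and reproducible", {
  x <- makeToyDesign(seed = 7)
  arms <- cutLocus(x$locus, x$pair)
  frag <- releaseDonor(paste0("CCTAGGAATT", donorSeq(x$design), "AATTCCTAGG"),
                       x$design)
  fwd <- insertFragment(arms$left, arms$right, frag, "forward")

  expect_identical(applyJunctionIndels(fwd, 0L, seed = 1)@alleleSeq,
                   fwd@alleleSeq)
  a <- applyJunctionIndels(fwd, 10L, seed = 42)
  b <- applyJunctionIndels(fwd, 10L, seed = 42)
  expect_identical(a@alleleSeq, b@alleleSeq)
  expect_true(all(abs(a@junctions$bp) <= 10L))
  c <- applyJunctionIndels(fwd, 10L, seed = 43)
  expect_false(identical(a@alleleSeq, c@alleleSeq))  # different seed moves it
})

test_that("transcript prediction reproduces WT, tagged and null products", {
  x <- makeToyDesign(seed = 8)
  locus <- unname(x$locus)
  expect <- expectedProduct(locus, x$model, x$cassette, x$insertionPoint)

  # independent construction of the tagged protein by string surgery
  insAA <- as.character(Biostrings::translate(
    Biostrings::DNAString(cassetteSeq(x$cassette))))
  spAA <- x$truth$signalPeptideAA
  byHand <- paste0(substr(expect$wtProtein, 1, spAA), insAA,
                   substr(expect$wtProtein, spAA + 1,
                          nchar(expect$wtProtein)))
  expect_equal(expect$taggedProtein, byHand)
  expect_equal(expect$tagInsertAAPos, spAA)

  out <- simulateOutcomes(x$locus, x$model, x$design)
  expect_equal(out$unedited@protein, expect$wtProtein)
  expect_equal(out$forward@protein, expect$taggedProtein)
  expect_equal(classification(out$forward), "KI")
  expect_equal(classification(out$reverse), "recuttable")
  expect_equal(out$ko@protein, "")
})

test_that("forward knock-in tolerates junction INDELs up to 10 bp", {
  x <- makeToyDesign(seed = 9)
  expect <- expectedProduct(unname(x$locus), x$model, x$cassette,
                            x$insertionPoint)
  for (seed in c(2, 12, 22, 32)) {
    out <- simulateOutcomes(x$locus, x$model, x$design,
                            maxIndel = 10L, seed = seed)
    expect_equal(out$forward@protein, expect$taggedProtein,
                 label = paste("protein under INDEL seed", seed))
    expect_equal(classification(out$forward), "KI")
  }
})

test_that("a forward knock-in allele is a terminal state (no re-cutting)", {
  x <- makeToyDesign(seed = 10)
  out <- simulateOutcomes(x$locus, x$model, x$design)
  ki <- out$forward
  # no intact site remains, so another round of cutting finds nothing
  expect_equal(nrow(detectIntactSites(ki@alleleSeq, x$pair, x$locus)), 0L)
})
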