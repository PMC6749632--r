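test_that("inversion length and Mb rounding follow the breakpoint convention", {
  len <- inversionLength(Breakpoint("X", 82271052), Breakpoint("X", 86034441))
  expect_equal(len$bp, 3763389)
  expect_equal(len$mb, 3.8)
  ## adjacent breakpoints
  adj <- inversionLength(Breakpoint("X", 100), Breakpoint("X", 101))
  expect_equal(adj$bp, 1)
  expect_equal(adj$mb, 0)
  expect_error(inversionLength(Breakpoint("X", 200), Breakpoint("X", 100)),
               "after")
  expect_error(inversionLength(Breakpoint("X", 100), Breakpoint("1", 200)),
               "different chromosomes")
})

test_that("junction classification reads off duplication, deletion and blunt joins", {
  ## duplication of a 12-bp motif copied from the left flank at the join
  jx <- simulateJunction(motif = "GTACAAGAAACT", seed = 207)
  call <- classifyJunction(jx$refLeftFlank, jx$refRightFlank, jx$junctionSeq)
  expect_equal(duplicatedLength(call), 12L)
  expect_identical(call@duplicatedSegment, "GTACAAGAAACT")
  expect_identical(mechanism(call), "MMBIR_like")
  expect_equal(deletedLength(call), 0L)
  ## loss of a single thymine with no homology
  jx2 <- simulateJunction(deletionLength = 1, deletedBases = "T", seed = 208)
  call2 <- classifyJunction(jx2$refLeftFlank, jx2$refRightFlank,
                            jx2$junctionSeq)
  expect_equal(deletedLength(call2), 1L)
  expect_identical(call2@deletedBases, "T")
  expect_identical(mechanism(call2), "NHEJ_like")
  ## exact end join
  jx3 <- simulateJunction(seed = 209)
  call3 <- classifyJunction(jx3$refLeftFlank, jx3$refRightFlank,
                            jx3$junctionSeq)
  expect_identical(mechanism(call3), "blunt")
  expect_equal(duplicatedLength(call3) + deletedLength(call3) +
                 nchar(call3@insertedBases), 0L)
  ## junction that anchors in neither flank
  bad <- classifyJunction(jx$refLeftFlank, jx$refRightFlank,
                          paste(rep("ACGT", 30), collapse = ""))
  expect_identical(mechanism(bad), "unresolved")
  expect_match(bad@diagnostics, "anchor")
})

test_that("junction round trip recovers every configured repair signature", {
  seed <- 300
  for (m in c(0L, 2L, 5L, 12L)) {
    for (d in c(0L, 1L, 3L)) {
      for (ins in c("", "ACGTA")) {
        seed <- seed + 1L
        jx <- simulateJunction(flankLength = 300, microhomologyLength = m,
                               deletionLength = d, insertion = ins,
                               seed = seed)
        call <- classifyJunction(jx$refLeftFlank, jx$refRightFlank,
                                 jx$junctionSeq)
        expect_equal(duplicatedLength(call), m)
        expect_equal(deletedLength(call), d)
        expect_identical(call@insertedBases, ins)
        expect_identical(mechanism(call), jx$truth$mechanism)
      }
    }
  }
})

test_that("a sub-threshold microhomology is NHEJ-like, a threshold one MMBIR-like", {
  jx <- simulateJunction(microhomologyLength = 1, seed = 401)
  expect_identical(jx$truth$mechanism, "NHEJ_like")
  call <- classifyJunction(jx$refLeftFlank, jx$refRightFlank, jx$junctionSeq)
  expect_identical(mechanism(call), "NHEJ_like")
  expect_equal(duplicatedLength(call), 1L)
  ## the same 2-bp homology flips with the configured minimum
  jx2 <- simulateJunction(microhomologyLength = 2, seed = 402)
  call2 <- classifyJunction(jx2$refLeftFlank, jx2$refRightFlank,
                            jx2$junctionSeq)
  expect_identical(mechanism(call2), "MMBIR_like")
  call3 <- classifyJunction(jx2$refLeftFlank, jx2$refRightFlank,
                            jx2$junctionSeq, minMicrohomology = 3)
  expect_identical(mechanism(call3), "NHEJ_like")
})

test_that("dotplot self-comparison yields the full main diagonal", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
             collapse = "")
  dm <- dotplotMatches(s, s, wordSize = 10, bothStrands = FALSE)
  diag_ <- dm[dm$i == dm$j, ]
  expect_equal(nrow(diag_), 100 - 10 + 1)
  ## symmetric under swapping inputs with coordinate transposition
  set.seed(6)
  t_ <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  ab <- dotplotMatches(s, t_, wordSize = 6)
  ba <- dotplotMatches(t_, s, wordSize = 6)
  expect_setequal(paste(ab$i, ab$j, ab$strand),
                  paste(ba$j, ba$i, ba$strand))
})

test_that("dotplot reverse-complement matches appear on the minus strand only", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  dm <- dotplotMatches(s, rc, wordSize = 12)
  expect_true(all(dm$strand == "-"))
  minus <- dm[dm$strand == "-", ]
  ## the self-vs-reverse-complement matches form the anti-diagonal
  ## j = nb - i - w + 2 in the original coordinates of b
  expect_true(all(seq_len(60 - 12 + 1) %in% minus$i))
  expect_equal(minus$j[match(seq_len(49), minus$i)], 50 - seq_len(49))
})

test_that("random-sequence dotplot match counts follow the closed-form expectation", {
  ## expected forward matches between two random 500-mers:
  ## (500 - 10 + 1)^2 * (1/4)^10
  lambda1 <- (491^2) / 4^10
  nSeeds <- 100
  total <- 0
  for (seed in seq_len(nSeeds)) {
    set.seed(10000 + seed)
    a <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    total <- total + nrow(dotplotMatches(a, b, wordSize = 10,
                                         bothStrands = FALSE))
  }
  lambda <- nSeeds * lambda1
  expect_gte(total, qpois(1e-5, lambda))
  expect_lte(total, qpois(1 - 1e-5, lambda))
})

test_that("dotplot handles N bases and too-short input", {
  dm <- dotplotMatches("ACGTNACGTNAC", "ACGTNACGTNAC", wordSize = 5,
                       bothStrands = FALSE)
  expect_equal(nrow(dm), 0L)  # every 5-mer contains an N
  expect_warning(out <- dotplotMatches("ACG", "ACGTACGT", wordSize = 6),
                 "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("depth windows tile, average and respect the mask", {
  ## constant per-base depth
  base <- data.frame(chrom = "X", pos = 1:30000, depth = 14)
  dp <- depthProfile(base, window = 10000)
  gr <- profileWindows(dp)
  expect_equal(length(gr), 3L)
  expect_true(all(gr$meanDepth == 14))
  ## mask flags windows intersecting BED intervals
  dp2 <- depthProfile(base, window = 10000,
                      mask = data.frame(chrom = "X", start = 12000,
                                        end = 15000))
  expect_identical(profileWindows(dp2)$masked, c(FALSE, TRUE, FALSE))
  ## per-base means are invariant to splitting the input into chunks
  set.seed(9)
  d <- data.frame(chrom = "X", pos = 1:20000, depth = rpois(20000, 14))
  whole <- profileWindows(depthProfile(d, window = 5000))$meanDepth
  expect_equal(whole,
               tapply(d$depth, (d$pos - 1) %/% 5000, mean),
               ignore_attr = TRUE)
  ## per-window input passes through
  sd1 <- simulateDepth(chromLength = 2e5, window = 10000, seed = 10)
  dpw <- depthProfile(sd1$depth, window = 10000)
  expect_equal(profileWindows(dpw)$meanDepth, sd1$depth$mean)
  expect_error(depthProfile(data.frame(chrom = "X", start = c(1, 4000),
                                       mean = c(10, 10)), window = 10000),
               "grid")
})

test_that("a copy-neutral Poisson profile stays within half of its global mean", {
  sd1 <- simulateDepth(chromLength = 6e6, window = 10000, baseMean = 13.8,
                       seed = 11)
  dp <- profileWindows(depthProfile(sd1$depth, window = 10000))
  expect_true(all(abs(dp$meanDepth - mean(dp$meanDepth)) <
                    0.5 * mean(dp$meanDepth)))
})

test_that("copy-number flag detects planted CNVs and stays quiet otherwise", {
  interval <- c(2000001, 4000000)
  neutral <- simulateDepth(chromLength = 6e6, seed = 12)
  dpN <- depthProfile(neutral$depth)
  cnN <- copyNumberFlag(dpN, interval)
  expect_true(cnN$neutral)
  expect_equal(cnN$ratio, 1, tolerance = 0.05)
  ## heterozygous deletion at half depth
  del <- simulateDepth(chromLength = 6e6,
                       cnv = data.frame(start = interval[1],
                                        end = interval[2], fold = 0.5),
                       seed = 13)
  cnD <- copyNumberFlag(depthProfile(del$depth), interval)
  expect_false(cnD$neutral)
  expect_equal(cnD$ratio, 0.5, tolerance = 0.05)
  ## a single-copy duplication has an expected ratio of exactly 1.5, on the
  ## default band edge; detecting it needs a threshold strictly below the
  ## expected ratio
  dup <- simulateDepth(chromLength = 6e6,
                       cnv = data.frame(start = interval[1],
                                        end = interval[2], fold = 1.5),
                       seed = 14)
  cnU <- copyNumberFlag(depthProfile(dup$depth), interval,
                        foldThreshold = 1.4)
  expect_false(cnU$neutral)
  expect_equal(cnU$ratio, 1.5, tolerance = 0.05)
  ## masked windows are excluded; an interval that is fully masked errors
  mask <- data.frame(chrom = "X", start = interval[1] - 1, end = interval[2])
  dpM <- depthProfile(neutral$depth, mask = mask)
  expect_error(copyNumberFlag(dpM, interval), "no unmasked window inside")
})
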