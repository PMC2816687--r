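test_that("nucleotide diversity matches hand-derivable micro-examples", {
  ident <- makeAln(stats::setNames(rep("ACGTACGT", 4), paste0("h", 1:4)))
  expect_equal(nucleotideDiversity(ident), 0)

  # n = 4, L = 10, one site split 2/2: 4 differing pairs of 6 -> (4/6)/10
  aln <- makeAln(c(h1 = "AAAAAAAAAA", h2 = "AAAAAAAAAA",
                   h3 = "AAAAAAAAAC", h4 = "AAAAAAAAAC"))
  expect_equal(nucleotideDiversity(aln), (4 / 6) / 10)

  pair <- makeAln(c(h1 = strrep("A", 100),
                    h2 = paste0(strrep("A", 99), "C")))
  expect_equal(nucleotideDiversity(pair), 0.01)
  expect_error(nucleotideDiversity(aln, "h1"), ">= 2 haplotypes")
})

test_that("pairwise-loop and frequency forms of pi agree without missing data", {
  set.seed(7)
  for (rep in 1:20) {
    aln <- randomAln(nHap = sample(4:12, 1), L = 30,
                     nVar = sample(3:10, 1))
    m <- as.matrix(aln@sequences)
    expect_equal(nucleotideDiversity(aln), piPairwiseLoop(m),
                 tolerance = 1e-12)
    expect_equal(nucleotideDiversity(aln), piFreqForm(m),
                 tolerance = 1e-9)
  }
})

test_that("missing bases are dropped pairwise with per-pair normalization", {
  # pair h1-h2: differs at col1 over 2 valid cols; h1-h3 identical over 2;
  # h2-h3: differ at col1 over length 2
  aln <- makeAln(c(h1 = "ACG", h2 = "TCN", h3 = "ANG"))
  # pairs: (h1,h2): cols 1,2 valid, 1 diff -> 1/2; (h1,h3): cols 1,3 -> 0/2;
  # (h2,h3): col 1 only -> 1/1
  expect_equal(nucleotideDiversity(aln), mean(c(1 / 2, 0, 1)))
})

test_that("Watterson's theta uses the harmonic-number denominator", {
  expect_equal(wattersonTheta(0, 10, 100), 0)
  expect_equal(wattersonTheta(14, 10, 1), 14 / sum(1 / (1:9)),
               tolerance = 1e-6)
  expect_equal(14 / sum(1 / (1:9)), 4.948805, tolerance = 1e-6)
  expect_equal(wattersonTheta(3, 2, 100), 0.03)
  expect_error(wattersonTheta(1, 1, 10), "n >= 2")
})

test_that("Tajima's D reproduces a step-by-step evaluation on a fixed fixture", {
  # 6 haplotypes, 12 columns, 5 segregating sites of mixed frequencies
  aln <- makeAln(c(h1 = "AAAAAAAAAAAA",
                   h2 = "AAAACAAAAAAA",
                   h3 = "ACAACAAAATAA",
                   h4 = "ACAACAAAATAA",
                   h5 = "ACGACAAAATAA",
                   h6 = "ACGACAAAATAC"))
  tc <- tajimasD(aln)
  n <- 6
  m <- as.matrix(aln@sequences)
  S <- sum(apply(m, 2, function(x) length(unique(x)) > 1))
  piTotal <- piPairwiseLoop(m) * ncol(m)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  Dexp <- (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_identical(tc$S, S)
  expect_equal(tc$piTotal, piTotal, tolerance = 1e-12)
  expect_equal(tc$a1, a1, tolerance = 1e-12)
  expect_equal(tc$e1, e1, tolerance = 1e-12)
  expect_equal(tc$e2, e2, tolerance = 1e-12)
  expect_equal(tc$D, Dexp, tolerance = 1e-12)
  expect_true(tc$Dmin < 0 && tc$Dmax > 0)
  expect_true(tc$e1 > 0 && tc$e2 > 0)
})

test_that("Tajima edge cases: no variation, small n, singleton excess", {
  mono <- makeAln(stats::setNames(rep("ACGT", 5), paste0("h", 1:5)))
  expect_true(is.na(tajimasD(mono)$D))
  expect_warning(small <- tajimasD(makeAln(c(h1 = "AC", h2 = "AG",
                                             h3 = "AG"))), "n < 4")
  expect_true(is.na(small$D))
  # all-singleton spectrum gives negative D
  m <- matrix(0L, 10, 10)
  diag(m) <- 1L
  expect_lt(tajimasD(m)$D, 0)
})

test_that("sign of D follows pi minus theta whenever defined", {
  set.seed(11)
  for (rep in 1:25) {
    m <- simulateCoalescentSample(sample(5:15, 1), theta = 4)
    if (ncol(m) == 0) next
    tc <- tajimasD(m)
    expect_identical(sign(tc$D), sign(tc$piTotal - tc$thetaW))
  }
})

test_that("beta-distribution p-values match numerical quadrature", {
  set.seed(21)
  for (rep in 1:10) {
    m <- simulateCoalescentSample(12, theta = 6)
    if (ncol(m) == 0) next
    tc <- tajimasD(m)
    expect_equal(tc$p, betaQuadraturePvalue(tc), tolerance = 1e-6)
  }
})

test_that("beta test is near 1 at D = 0 and small at the support edge", {
  tc <- tajimasD(simulateCoalescentSample(10, theta = 5, seed = 2))
  tc$D <- 0
  expect_gt(tajimaBetaPvalue(tc), 0.85)
  tc$D <- tc$Dmax - 1e-6
  expect_lt(tajimaBetaPvalue(tc), 0.05)
  tc$D <- tc$Dmax + 1
  expect_warning(pclamp <- tajimaBetaPvalue(tc), "clamped")
  expect_lt(pclamp, 0.01)
})

test_that("Hudson FST matches hand-derived fixtures", {
  # two samples with identical sequence multisets: the distinct-pair
  # estimator gives exactly -1/(n-1) (within-pairs exclude self-pairs but
  # between-pairs cannot), vanishing as n grows
  for (n in c(10L, 40L)) {
    half <- stats::setNames(rep(c("AC", "AG"), n / 2),
                            paste0("a", seq_len(n)))
    seqs <- c(half, stats::setNames(unname(half), paste0("b", seq_len(n))))
    f <- hudsonFst(makeAln(seqs), paste0("a", seq_len(n)),
                   paste0("b", seq_len(n)))
    expect_equal(f$fst, -1 / (n - 1), tolerance = 1e-12)
  }
  # fixed difference, no within variation
  seqs <- c(a1 = "A", a2 = "A", b1 = "C", b2 = "C")
  f <- hudsonFst(makeAln(seqs), c("a1", "a2"), c("b1", "b2"))
  expect_equal(f$Hw, 0)
  expect_equal(f$fst, 1)
  # single site, 9A/1a vs 1A/9a: Hw = 0.2, Hb = 0.82
  seqs <- stats::setNames(c(rep("A", 9), "C", "A", rep("C", 9)),
                          c(paste0("a", 1:10), paste0("b", 1:10)))
  f <- hudsonFst(makeAln(seqs), paste0("a", 1:10), paste0("b", 1:10))
  expect_equal(f$Hw, 0.2)
  expect_equal(f$Hb, 0.82)
  expect_equal(f$fst, 0.756098, tolerance = 1e-6)
  expect_error(hudsonFst(makeAln(seqs), "a1", paste0("b", 1:10)),
               ">= 2 haplotypes")
})

test_that("FST is invariant to relabeling; duplication shifts it predictably", {
  set.seed(13)
  aln <- randomAln(nHap = 12, L = 40, nVar = 8)
  A <- paste0("h", 1:6)
  B <- paste0("h", 7:12)
  f1 <- hudsonFst(aln, A, B)
  f2 <- hudsonFst(aln, B, A)
  expect_equal(f1$fst, f2$fst, tolerance = 1e-12)
  expect_equal(f1$Hw, f2$Hw, tolerance = 1e-12)
  # duplicating every haplotype leaves Hb untouched and scales the
  # within-pair mean by exactly 2(n-1)/(2n-1) (the new zero-distance
  # self-pairs), so the estimator is duplication-invariant only as n grows
  m <- as.matrix(aln@sequences)
  seqs2 <- apply(m[rep(1:12, each = 2), ], 1, paste0, collapse = "")
  names(seqs2) <- paste0("d", 1:24)
  dup <- makeAln(seqs2)
  f3 <- hudsonFst(dup, names(seqs2)[1:12], names(seqs2)[13:24])
  n <- 6
  expect_equal(f3$Hb, f1$Hb, tolerance = 1e-12)
  expect_equal(f3$Hw, f1$Hw * 2 * (n - 1) / (2 * n - 1), tolerance = 1e-12)
  expect_equal(f3$fst, 1 - (1 - f1$fst) * 2 * (n - 1) / (2 * n - 1),
               tolerance = 1e-12)
})

test_that("per-locus popgen tables carry both populations", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 8, nIndividuals = 6,
    loci = data.frame(locus = "L1", region = "HmYb", length = 200L,
                      nSites = 8L, offset = 1L, stringsAsFactors = FALSE),
    selectedSites = data.frame(locus = character(0), column = integer(0),
                               pPopA = numeric(0), pPopB = numeric(0))))
  tab <- locusPopgenTable(sim$alignments[[1]],
                          list(aglaope = sim$popHaplotypes$popA,
                               amaryllis = sim$popHaplotypes$popB))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$pi_per_bp >= 0))
  expect_true(all(tab$S >= 0))
  expect_identical(tab$n_haplotypes, c(12L, 12L))
})
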