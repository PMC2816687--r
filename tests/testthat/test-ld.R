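test_that("composite delta and r2 match hand-derived fixtures", {
  # 5 individuals AABB + 5 aabb: n_AB term 1.0, 2 pA pB = 0.5
  dA <- c(rep(1, 5), rep(0, 5))
  expect_equal(compositeDelta(dA, dA), 0.5)
  expect_equal(compositeR2(dA, dA), 1)

  di <- c(2, 2, 1, 1, 0) / 2
  dj <- c(2, 1, 1, 2, 0) / 2
  expect_equal(compositeDelta(di, dj), 0.18)
  expect_equal(compositeR2(di, dj), 0.413265, tolerance = 1e-6)
  expect_equal(compositeR2(di, di), 1)

  expect_true(is.na(compositeDelta(rep(0.5, 5), di)))
  expect_error(compositeDelta(c(1, NA), c(NA, 1)), "complete pairs")
})

test_that("r2 equals the Burrows-formula route on random fixtures", {
  set.seed(41)
  checked <- 0
  while (checked < 120) {
    n <- sample(10:40, 1)
    di <- sample(c(0, 0.5, 1), n, replace = TRUE)
    dj <- sample(c(0, 0.5, 1), n, replace = TRUE)
    if (sd(di) == 0 || sd(dj) == 0) next
    expect_equal(compositeR2(di, dj), compositeR2Formula(di, dj),
                 tolerance = 1e-12)
    expect_equal(compositeR2(di, dj), stats::cor(di, dj)^2,
                 tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("r2 is symmetric and invariant to allele-orientation flips", {
  set.seed(43)
  for (rep in 1:20) {
    di <- sample(c(0, 0.5, 1), 25, replace = TRUE)
    dj <- sample(c(0, 0.5, 1), 25, replace = TRUE)
    if (sd(di) == 0 || sd(dj) == 0) next
    expect_equal(compositeR2(di, dj), compositeR2(dj, di),
                 tolerance = 1e-12)
    expect_equal(compositeR2(1 - di, dj), compositeR2(di, dj),
                 tolerance = 1e-12)
    expect_equal(compositeDelta(1 - di, dj), -compositeDelta(di, dj),
                 tolerance = 1e-12)
  }
})

test_that("composite r2 tracks haplotype r2 under random mating", {
  set.seed(47)
  gaps <- replicate(500, {
    pA <- runif(1, 0.2, 0.8)
    pB <- runif(1, 0.2, 0.8)
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
    D <- runif(1, -min(pA * pB, (1 - pA) * (1 - pB)), dmax)
    probs <- c(pA * pB + D, pA * (1 - pB) - D,
               (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D)
    haps <- sample(1:4, 100, replace = TRUE, prob = probs)
    hA <- as.numeric(haps %in% c(1, 2))   # carries allele A at locus 1
    hB <- as.numeric(haps %in% c(1, 3))
    # true haplotype r2 from the phased sample
    if (sd(hA) == 0 || sd(hB) == 0) return(NA_real_)
    hapR2 <- stats::cor(hA, hB)^2
    # random mating: pair consecutive haplotypes into 50 diploids
    di <- (hA[seq(1, 99, 2)] + hA[seq(2, 100, 2)]) / 2
    dj <- (hB[seq(1, 99, 2)] + hB[seq(2, 100, 2)]) / 2
    if (sd(di) == 0 || sd(dj) == 0) return(NA_real_)
    abs(compositeR2(di, dj) - hapR2)
  })
  expect_lt(mean(gaps, na.rm = TRUE), 0.05)
})

test_that("ldMatrix enumerates pairs and applies the minimum-n rule", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 51, nIndividuals = 15,
    loci = data.frame(locus = "L1", region = "HmB", length = 100L,
                      nSites = 3L, offset = 1L, stringsAsFactors = FALSE),
    selectedSites = data.frame(locus = character(0), column = integer(0),
                               pPopA = numeric(0), pPopB = numeric(0)),
    backgroundFreq = function(k) rep(0.5, k)))
  gm <- genotypeMatrixFromAlignments(sim$alignments, sim$samples)
  ld <- ldMatrix(gm, minN = 20)
  expect_identical(nrow(ld), 3L)          # C(3,2)
  expect_true(all(ld$n_used == 30))
  expect_true(all(is.finite(ld$r2) | ld$reason == "monomorphic"))
  # insufficient sample size: only 19 complete individuals
  d <- dosage(gm)
  d[1:11, 1] <- NA
  gm2 <- new("GenotypeMatrix", dosage = d, siteInfo = siteInfo(gm))
  ld2 <- ldMatrix(gm2, minN = 20)
  touching <- ld2$site_i == colnames(d)[1] | ld2$site_j == colnames(d)[1]
  expect_true(all(is.na(ld2$r2[touching])))
  expect_true(all(ld2$reason[touching] == "insufficient_n"))
  expect_identical(ld2$n_used[touching], c(19L, 19L))
})

test_that("pooled-population LD equals direct computation on the merged matrix", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 53, nIndividuals = 12,
    loci = data.frame(locus = "L1", region = "HmB", length = 150L,
                      nSites = 5L, offset = 1L, stringsAsFactors = FALSE)))
  gm <- genotypeMatrixFromAlignments(sim$alignments, sim$samples)
  ld <- ldMatrix(filterInformative(gm), minN = 2)
  d <- dosage(filterInformative(gm))
  for (k in seq_len(nrow(ld))) {
    if (is.na(ld$r2[k])) next
    expect_equal(ld$r2[k],
                 compositeR2(d[, ld$site_i[k]], d[, ld$site_j[k]]),
                 tolerance = 1e-12)
  }
})

test_that("distances come from the shared coordinate axis, NA without offsets", {
  loci <- data.frame(locus = c("A1", "A2"), region = c("HmB", "unlinked"),
                     length = 50L, nSites = 2L, offset = c(101L, NA),
                     stringsAsFactors = FALSE)
  sim <- simulateTwoPopDataset(synthConfig(seed = 55, nIndividuals = 12,
    loci = loci,
    selectedSites = data.frame(locus = character(0), column = integer(0),
                               pPopA = numeric(0), pPopB = numeric(0)),
    backgroundFreq = function(k) rep(0.5, k)))
  gm <- genotypeMatrixFromAlignments(sim$alignments, sim$samples)
  ld <- ldMatrix(gm, minN = 2)
  within <- ld$within_gene & ld$locus_i == "A1"
  expect_true(all(!is.na(ld$distance[within])))
  crossing <- ld$locus_i != ld$locus_j
  expect_true(all(is.na(ld$distance[crossing])))
})

test_that("decay binning averages r2 per distance bin and keeps empty bins", {
  rec <- data.frame(site_i = "a", site_j = "b", locus_i = "L", locus_j = "L",
                    pos_i = 1L, pos_j = 101L, distance = 100,
                    within_gene = TRUE, n_used = 30L, delta = 0.1,
                    r2 = 0.4, reason = NA, pair_class = "other",
                    stringsAsFactors = FALSE)
  dec <- ldDecay(rec, c(0, 200))
  expect_equal(dec$mean_r2, 0.4)
  expect_identical(dec$n_pairs, 1L)
  dec2 <- ldDecay(rec, c(0, 50, 150, 500))
  expect_identical(dec2$n_pairs, c(0L, 1L, 0L))
  expect_true(is.na(dec2$mean_r2[1]) && is.na(dec2$mean_r2[3]))
  rec$distance <- NA
  expect_error(ldDecay(rec, c(0, 200)), "no LD records")
})

test_that("block simulation yields higher r2 within the block than beyond it", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 57))
  gm <- filterInformative(
    genotypeMatrixFromAlignments(sim$alignments, sim$samples))
  ld <- ldMatrix(gm, minN = 20)
  dec <- ldDecay(ld, c(0, 14000, 60000))
  expect_gt(dec$mean_r2[1], dec$mean_r2[2])
})

test_that("association partitioning classifies and filters pairs by set logic", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 59))
  gm <- filterInformative(
    genotypeMatrixFromAlignments(sim$alignments, sim$samples))
  scan <- associationScan(gm, scorePhenotypes(sim$samples))
  ld <- partitionSitesByAssociation(ldMatrix(gm, minN = 20), scan)
  sigSites <- scan$site[scan$significant]
  both <- ld$site_i %in% sigSites & ld$site_j %in% sigSites
  expect_identical(ld$pair_class == "both_associated", both)
  one <- xor(ld$site_i %in% sigSites, ld$site_j %in% sigSites)
  expect_true(all(ld$pair_class[one] == "other"))
  # "associated removed" excludes every pair touching a significant site
  clean <- excludeAssociatedPairs(ld)
  expect_false(any(clean$site_i %in% sigSites |
                     clean$site_j %in% sigSites))
  # sites without an association record warn and class as other
  expect_warning(partitionSitesByAssociation(ld, scan[-1, ]),
                 "without an association record")
})

test_that("removing associated sites collapses long-distance LD to background", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 61))
  gm <- filterInformative(
    genotypeMatrixFromAlignments(sim$alignments, sim$samples))
  scan <- associationScan(gm, scorePhenotypes(sim$samples))
  ld <- partitionSitesByAssociation(ldMatrix(gm, minN = 20), scan)
  far <- !is.na(ld$distance) & ld$distance > 5000 & !is.na(ld$r2)
  allFar <- mean(ld$r2[far])
  clean <- excludeAssociatedPairs(ld)
  farC <- !is.na(clean$distance) & clean$distance > 5000 & !is.na(clean$r2)
  expect_lt(mean(clean$r2[farC]), 0.3)
  expect_gt(allFar, mean(clean$r2[farC]))
})

test_that("the square r2 matrix is symmetric with unit diagonal", {
  sim <- simulateTwoPopDataset(synthConfig(seed = 63, nIndividuals = 12,
    loci = data.frame(locus = "L1", region = "HmB", length = 120L,
                      nSites = 4L, offset = 1L, stringsAsFactors = FALSE)))
  gm <- genotypeMatrixFromAlignments(sim$alignments, sim$samples)
  m <- ldSquareMatrix(ldMatrix(gm, minN = 2))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
})
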