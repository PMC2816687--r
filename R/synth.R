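# Synthetic two-population datasets with the statistical structure the
# hybrid-zone analyses assume, plus a neutral coalescent for null
# calibration and a closed-form FST oracle.

#' Configuration for the two-population simulator
#'
#' Defaults emulate the study conditions of the banded/rayed hybrid-zone
#' comparison: 30 diploid individuals per population; eight colour-pattern
#' -linked loci plus three unlinked loci carrying 40 and 20 variant sites
#' respectively; selected sites fixed (or nearly so) in the banded
#' population with the derived variant at frequency 0.05 in the rayed one,
#' the strongest five clustered in one haplotype block spanning under
#' 14 kb; neutral sites share a common frequency drawn from
#' Uniform(0.1, 0.9) in both populations.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   datasets.
#' @param nIndividuals diploid individuals per population (default 30).
#' @param loci data.frame with columns \code{locus}, \code{region},
#'   \code{length} (bp), \code{nSites}, \code{offset} (bp or NA);
#'   \code{NULL} for the defaults above.
#' @param selectedSites data.frame with columns \code{locus},
#'   \code{column} (0-based), \code{pPopA}, \code{pPopB} (derived-allele
#'   frequencies per population); \code{NULL} for the defaults.
#' @param backgroundFreq function(k) returning k shared neutral-site
#'   frequencies.
#' @param blockLength bp span within which selected sites are inherited
#'   jointly from one of two block haplotypes (default 14000).
#' @param missingRate per-base probability of an N call (default 0).
#' @param nAdmixed admixed individuals drawing one haplotype per
#'   population, phenotype-scored 0.5 (default 0).
#' @param popNames names of the two populations (popA is scored 0.0,
#'   popB 1.0).
#' @param comparison comparison label for the sample table.
#' @return A validated list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(seed = 1L,
                        nIndividuals = 30L,
                        loci = NULL,
                        selectedSites = NULL,
                        backgroundFreq = function(k) runif(k, 0.1, 0.9),
                        blockLength = 14000,
                        missingRate = 0,
                        nAdmixed = 0L,
                        popNames = c("aglaope", "amaryllis"),
                        comparison = "agl_ama") {
  defaultLoci <- is.null(loci)
  if (is.null(loci)) {
    loci <- data.frame(
      locus = c(paste0("B", 1:8), paste0("U", 1:3)),
      region = c(rep("HmB", 8), rep("unlinked", 3)),
      length = 650L,
      nSites = c(rep(5L, 8), 7L, 7L, 6L),
      offset = c(1L, 8001L, 16001L, 22001L, 28001L, 36001L, 44001L,
                 52001L, NA, NA, NA),
      stringsAsFactors = FALSE)
  }
  if (is.null(selectedSites)) {
    # the default selected-site spec belongs to the default loci; custom
    # loci default to an all-neutral dataset
    selectedSites <- if (defaultLoci) {
      data.frame(
        locus = c("B3", "B3", "B4", "B4", "B5",
                  "B1", "B2", "B6", "B7", "B8"),
        column = c(100L, 300L, 150L, 400L, 250L,
                   200L, 200L, 200L, 200L, 200L),
        pPopA = c(rep(0.05, 5), rep(0.2, 5)),
        pPopB = c(rep(1.0, 5), rep(0.8, 5)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(locus = character(0), column = integer(0),
                 pPopA = numeric(0), pPopB = numeric(0),
                 stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.function(backgroundFreq), blockLength >= 0,
            missingRate >= 0, missingRate < 1,
            length(popNames) == 2L, nIndividuals >= 1L)
  if (nrow(selectedSites) > 0L) {
    if (any(selectedSites$pPopA < 0 | selectedSites$pPopA > 1 |
            selectedSites$pPopB < 0 | selectedSites$pPopB > 1)) {
      stop("selected-site frequencies must lie in [0, 1]")
    }
    if (any(!selectedSites$locus %in% loci$locus)) {
      stop("selected site refers to an unknown locus")
    }
    if (any(selectedSites$column >= loci$length[
          match(selectedSites$locus, loci$locus)])) {
      stop("selected site column beyond locus length")
    }
  }
  structure(list(seed = as.integer(seed),
                 nIndividuals = as.integer(nIndividuals),
                 loci = loci, selectedSites = selectedSites,
                 backgroundFreq = backgroundFreq,
                 blockLength = blockLength,
                 missingRate = missingRate,
                 nAdmixed = as.integer(nAdmixed),
                 popNames = popNames, comparison = comparison),
            class = "SynthConfig")
}

# group selected sites into haplotype blocks on the shared coordinate axis;
# sites without an offset (or farther than blockLength from the running
# block start) open a new block
.selectedBlocks <- function(cfg) {
  ss <- cfg$selectedSites
  if (nrow(ss) == 0L) return(list())
  off <- cfg$loci$offset[match(ss$locus, cfg$loci$locus)]
  pos <- ifelse(is.na(off), NA_real_, off + ss$column)
  ord <- order(is.na(pos), pos)
  ss <- ss[ord, , drop = FALSE]
  pos <- pos[ord]
  blocks <- list()
  cur <- integer(0)
  start <- NA_real_
  for (i in seq_len(nrow(ss))) {
    newBlock <- is.na(pos[i]) || is.na(start) ||
      (pos[i] - start) > cfg$blockLength
    if (newBlock) {
      if (length(cur) > 0L) blocks[[length(blocks) + 1L]] <- cur
      cur <- i
      start <- pos[i]
    } else {
      cur <- c(cur, i)
    }
    if (is.na(pos[i])) {             # offset-less sites never share a block
      blocks[[length(blocks) + 1L]] <- cur
      cur <- integer(0)
      start <- NA_real_
    }
  }
  if (length(cur) > 0L) blocks[[length(blocks) + 1L]] <- cur
  lapply(blocks, function(ix) ss[ix, , drop = FALSE])
}

#' Simulate a two-population diploid dataset
#'
#' Draws haplotypes per population: neutral sites are independent with a
#' frequency shared between populations; selected sites have
#' population-specific derived-allele frequencies and, within a haplotype
#' block, are inherited jointly from one of two block haplotypes (creating
#' long-range LD among phenotype-associated sites). Diploids are formed by
#' pairing consecutive haplotypes; phenotype scores follow population
#' (popA = 0.0, popB = 1.0), with optional admixed individuals carrying one
#' haplotype from each population and scored 0.5.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list of class \code{"SimulatedDataset"}: \code{alignments}
#'   (named list of \code{\linkS4class{LocusAlignment}}), \code{samples}
#'   (sample-table data.frame), \code{locusMeta},
#'   \code{popHaplotypes} (list popA/popB haplotype names, admixed
#'   excluded), and \code{selectedPositions} (locus/column/position of the
#'   selected sites).
#' @export
simulateTwoPopDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  nI <- cfg$nIndividuals
  pops <- cfg$popNames
  indA <- sprintf("%s_%02d", pops[1], seq_len(nI))
  indB <- sprintf("%s_%02d", pops[2], seq_len(nI))
  indH <- if (cfg$nAdmixed > 0L) {
    sprintf("admix_%02d", seq_len(cfg$nAdmixed))
  } else character(0)
  ind <- c(indA, indB, indH)
  hap1 <- paste0(ind, "_a")
  hap2 <- paste0(ind, "_b")
  haps <- as.vector(rbind(hap1, hap2))
  # population of origin per haplotype; admixed carry one of each
  origin <- c(rep(pops[1], 2L * nI), rep(pops[2], 2L * nI),
              rep(pops, length.out = 2L * cfg$nAdmixed))
  names(origin) <- as.vector(rbind(hap1, hap2))
  nH <- length(origin)
  bases <- c("A", "C", "G", "T")
  loci <- cfg$loci
  alleleMat <- list()   # locus -> logical matrix nH x nSites (derived?)
  siteCols <- list()
  ancestral <- list()
  derived <- list()
  selIdx <- split(seq_len(nrow(cfg$selectedSites)),
                  cfg$selectedSites$locus)
  for (li in seq_len(nrow(loci))) {
    lid <- loci$locus[li]
    L <- loci$length[li]
    anc <- sample(bases, L, replace = TRUE)
    selCols <- integer(0)
    if (lid %in% names(selIdx)) {
      selCols <- cfg$selectedSites$column[selIdx[[lid]]] + 1L
    }
    nNeutral <- loci$nSites[li] - length(selCols)
    if (nNeutral < 0L) stop("more selected sites than nSites at ", lid)
    free <- setdiff(seq_len(L), selCols)
    neuCols <- sort(sample(free, nNeutral))
    cols <- sort(c(selCols, neuCols))
    der <- vapply(cols, function(cl) sample(setdiff(bases, anc[cl]), 1),
                  character(1))
    mat <- matrix(FALSE, nH, length(cols),
                  dimnames = list(names(origin), NULL))
    pShared <- cfg$backgroundFreq(length(neuCols))
    for (k in seq_along(neuCols)) {
      j <- match(neuCols[k], cols)
      mat[, j] <- stats::rbinom(nH, 1L, pShared[k]) == 1L
    }
    alleleMat[[lid]] <- mat
    siteCols[[lid]] <- cols
    ancestral[[lid]] <- anc
    derived[[lid]] <- der
  }
  # selected sites: one Bernoulli draw per haplotype per block
  for (blk in .selectedBlocks(cfg)) {
    pA <- mean(blk$pPopA)
    pB <- mean(blk$pPopB)
    p <- ifelse(origin == pops[1], pA, pB)
    z <- stats::rbinom(nH, 1L, p) == 1L
    for (i in seq_len(nrow(blk))) {
      lid <- blk$locus[i]
      j <- match(blk$column[i] + 1L, siteCols[[lid]])
      alleleMat[[lid]][, j] <- z
    }
  }
  alignments <- vector("list", nrow(loci))
  names(alignments) <- loci$locus
  for (li in seq_len(nrow(loci))) {
    lid <- loci$locus[li]
    L <- loci$length[li]
    chars <- matrix(rep(ancestral[[lid]], each = nH), nrow = nH)
    cols <- siteCols[[lid]]
    for (k in seq_along(cols)) {
      chars[alleleMat[[lid]][, k], cols[k]] <- derived[[lid]][k]
    }
    if (cfg$missingRate > 0) {
      mask <- matrix(stats::runif(nH * L) < cfg$missingRate, nH, L)
      chars[mask] <- "N"
    }
    seqs <- apply(chars, 1L, paste0, collapse = "")
    names(seqs) <- names(origin)
    alignments[[lid]] <- LocusAlignment(
      lid, seqs, region = loci$region[li],
      genomicOffset = loci$offset[li])
  }
  samples <- data.frame(
    individual_id = ind,
    population = c(rep(pops[1], nI), rep(pops[2], nI),
                   rep("admixed", cfg$nAdmixed)),
    comparison = cfg$comparison,
    phenotype_score = c(rep(0, nI), rep(1, nI), rep(0.5, cfg$nAdmixed)),
    hap1 = hap1, hap2 = hap2,
    stringsAsFactors = FALSE)
  locusMeta <- data.frame(locus_id = loci$locus, region = loci$region,
                          genomic_offset = loci$offset,
                          notes = "synthetic",
                          stringsAsFactors = FALSE)
  selOff <- loci$offset[match(cfg$selectedSites$locus, loci$locus)]
  selectedPositions <- data.frame(
    locus = cfg$selectedSites$locus,
    column = cfg$selectedSites$column,
    position = ifelse(is.na(selOff), NA_integer_,
                      selOff + cfg$selectedSites$column),
    stringsAsFactors = FALSE)
  structure(list(alignments = alignments, samples = samples,
                 locusMeta = locusMeta,
                 popHaplotypes = list(
                   popA = as.vector(rbind(hap1, hap2))[
                     origin == pops[1] &
                       !grepl("^admix", names(origin))],
                   popB = as.vector(rbind(hap1, hap2))[
                     origin == pops[2] &
                       !grepl("^admix", names(origin))]),
                 selectedPositions = selectedPositions,
                 config = cfg),
            class = "SimulatedDataset")
}

#' Neutral coalescent sample under infinite sites
#'
#' Standard n-coalescent without recombination: while k lineages remain,
#' an exponential waiting time with rate \eqn{\binom{k}{2}} accrues on
#' every active branch and a uniformly chosen pair coalesces. Mutations
#' are Poisson with mean \eqn{\theta/2} times the total branch length,
#' each placed on a branch with probability proportional to its length and
#' carried by the tips below it (infinite sites: one column per mutation).
#' The expected number of segregating sites is
#' \eqn{\theta \sum_{i=1}^{n-1} 1/i}.
#'
#' @param n number of haplotypes (>= 2).
#' @param theta scaled mutation rate (> 0).
#' @param seed optional RNG seed.
#' @return 0/1 integer matrix, n rows (haplotypes) by S columns (sites);
#'   zero columns when no mutation fell on the tree.
#' @export
simulateCoalescentSample <- function(n, theta, seed = NULL) {
  stopifnot(n >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  members <- as.list(seq_len(n))
  lens <- numeric(n)
  segMembers <- list()
  segLens <- numeric(0)
  k <- n
  while (k > 1L) {
    lens <- lens + stats::rexp(1L, k * (k - 1) / 2)
    pr <- sort(sample.int(k, 2L))
    i <- pr[1]; j <- pr[2]
    segMembers <- c(segMembers, members[i], members[j])
    segLens <- c(segLens, lens[i], lens[j])
    members[[i]] <- c(members[[i]], members[[j]])
    lens[i] <- 0
    members[[j]] <- NULL
    lens <- lens[-j]
    k <- k - 1L
  }
  total <- sum(segLens)
  S <- stats::rpois(1L, theta / 2 * total)
  mat <- matrix(0L, n, S)
  if (S > 0L) {
    br <- sample.int(length(segLens), S, replace = TRUE, prob = segLens)
    for (s in seq_len(S)) mat[segMembers[[br[s]]], s] <- 1L
  }
  mat
}

#' Closed-form single-site Hudson FST expectation
#'
#' Plugs the expected within- and between-population heterozygosities of a
#' single biallelic site into \eqn{1 - H_w/H_b}: with unbiased sample
#' estimators of the pairwise-difference probabilities the sample sizes
#' cancel, giving
#' \eqn{1 - (p_A q_A + p_B q_B) / (p_A q_B + q_A p_B)}. Serves as the
#' analytic oracle for the simulated FST tests.
#'
#' @param pA,pB derived-allele frequencies in the two populations.
#' @param nA,nB sample sizes (accepted for interface symmetry; they cancel
#'   in expectation).
#' @return expected FST; \code{NA} when the expected \eqn{H_b} is 0.
#' @export
expectedHudsonFst <- function(pA, pB, nA = NULL, nB = NULL) {
  stopifnot(pA >= 0, pA <= 1, pB >= 0, pB <= 1)
  Hw <- pA * (1 - pA) + pB * (1 - pB)
  Hb <- pA * (1 - pB) + (1 - pA) * pB
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}
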