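# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different algebra/code paths than the package.

# build a LocusAlignment from a named character vector of sequences
makeAln <- function(seqs, locus = "locus1", region = "unlinked",
                    offset = NA_integer_) {
  LocusAlignment(locus, seqs, region = region, genomicOffset = offset)
}

# a single-column alignment realizing given per-haplotype bases
makeSiteAln <- function(bases, prefix = "h", ...) {
  makeAln(stats::setNames(bases, paste0(prefix, seq_along(bases))), ...)
}

# random gap-free alignment with k variable columns, no missing data
randomAln <- function(nHap, L, nVar, locus = "r1") {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  m <- matrix(rep(anc, each = nHap), nrow = nHap)
  cols <- sample(L, nVar)
  for (cl in cols) {
    der <- sample(setdiff(bases, anc[cl]), 1)
    carriers <- sample(nHap, sample(seq_len(nHap - 1L), 1))
    m[carriers, cl] <- der
  }
  seqs <- apply(m, 1, paste0, collapse = "")
  makeAln(stats::setNames(seqs, paste0("h", seq_len(nHap))), locus = locus)
}

# pi by explicit pairwise difference loop (independent of the package's
# crossproduct computation); no missing data assumed
piPairwiseLoop <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(m[i, ] != m[j, ])
    }
  }
  tot / choose(n, 2) / L
}

# pi from per-site allele frequencies: sum_s n/(n-1) (1 - sum p^2) / L
piFreqForm <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  tot <- 0
  for (s in seq_len(L)) {
    p <- table(m[, s]) / n
    tot <- tot + n / (n - 1) * (1 - sum(p^2))
  }
  tot / L
}

# composite r^2 through the Burrows-formula route: delta over the
# HW-departure-corrected denominator, from genotype-class counts
compositeR2Formula <- function(di, dj) {
  x <- 2 * di
  y <- 2 * dj
  n <- length(x)
  pA <- sum(x) / (2 * n)
  pB <- sum(y) / (2 * n)
  # Burrows count formula: (1/n) sum x_i y_i / 2 - 2 pA pB
  delta <- sum(x * y) / (2 * n) - 2 * pA * pB
  DA <- mean(x == 2) - pA^2
  DB <- mean(y == 2) - pB^2
  r <- delta / sqrt((pA * (1 - pA) + DA) * (pB * (1 - pB) + DB))
  r^2
}

# Mann-Whitney U via pair counting (x_i > y_j, halves for ties) and exact
# two-sided p by enumerating group assignments of the pooled values
mwPairCountU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

mwEnumOracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u <- mwPairCountU(x, y)
  mu <- n1 * (N - n1) / 2
  sets <- utils::combn(N, n1)
  uAll <- apply(sets, 2, function(ix) {
    mwPairCountU(pooled[ix], pooled[-ix])
  })
  list(U = u, p = mean(abs(uAll - mu) >= abs(u - mu) - 1e-9))
}

# BMA inclusion probabilities re-enumerated with lm() formulas
bmaOracle <- function(y, cov, cands = colnames(cov)) {
  K <- length(cands)
  n <- length(y)
  bics <- numeric(2^K)
  contains <- matrix(FALSE, 2^K, K)
  dat <- cbind(cov, .y = y)
  for (m in 0:(2^K - 1)) {
    inset <- as.logical(bitwAnd(m, 2^(0:(K - 1))))
    contains[m + 1, ] <- inset
    f <- if (any(inset)) {
      stats::as.formula(paste(".y ~", paste(cands[inset], collapse = "+")))
    } else .y ~ 1
    fit <- stats::lm(f, data = dat)
    rss <- sum(stats::resid(fit)^2)
    bics[m + 1] <- n * log(rss / n) + length(stats::coef(fit)) * log(n)
  }
  w <- exp(-(bics - min(bics)) / 2)
  w <- w / sum(w)
  stats::setNames(100 * as.numeric(t(w) %*% contains), cands)
}

# numerical-quadrature two-tailed p for the scaled beta null of Tajima's D
betaQuadraturePvalue <- function(tc) {
  a <- tc$Dmin
  b <- tc$Dmax
  alpha <- -(1 + a * b) * b / (b - a)
  beta <- (1 + a * b) * a / (b - a)
  lognorm <- lgamma(alpha + beta) - lgamma(alpha) - lgamma(beta) -
    (alpha + beta - 1) * log(b - a)
  dens <- function(D) exp(lognorm + (alpha - 1) * log(b - D) +
                            (beta - 1) * log(D - a))
  lower <- stats::integrate(dens, a, tc$D, rel.tol = 1e-10)$value
  2 * min(lower, 1 - lower)
}

# all-neutral two-population config (no selected sites)
neutralConfig <- function(seed, nLoci = 4L, length = 2500L,
                          nSites = 500L, nIndividuals = 30L) {
  loci <- data.frame(locus = paste0("L", seq_len(nLoci)),
                     region = "unlinked", length = length,
                     nSites = nSites, offset = NA_integer_,
                     stringsAsFactors = FALSE)
  synthConfig(seed = seed, nIndividuals = nIndividuals, loci = loci,
              selectedSites = data.frame(locus = character(0),
                                         column = integer(0),
                                         pPopA = numeric(0),
                                         pPopB = numeric(0)))
}
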