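# Diversity and neutrality statistics.
#
# All statistics operate on gap-trimmed alignments (columns containing any
# "-" are dropped entirely) and use pairwise deletion for missing bases:
# for each haplotype pair, columns where either base is N are dropped and
# the difference count is normalized by that pair's retained length.

# per-pair counts of valid (both non-N) columns and of differing valid
# columns, via indicator-matrix crossproducts
.pairStats <- function(m) {
  V <- (m != "N") * 1
  Lm <- tcrossprod(V)
  Mm <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T", "-")) {
    I <- (m == b) * 1
    Mm <- Mm + tcrossprod(I)
  }
  list(D = Lm - Mm, L = Lm)
}

# per-pair difference proportions between rows of m1 and rows of m2
# (m2 = NULL means within-m1 unordered pairs); NaN when a pair shares no
# valid column (dropped downstream by na.rm)
.pairDiffProps <- function(m1, m2 = NULL) {
  if (is.null(m2)) {
    if (nrow(m1) < 2L) return(numeric(0))
    ps <- .pairStats(m1)
    p <- ps$D / ps$L
    p[upper.tri(p)]
  } else {
    ps <- .pairStats(rbind(m1, m2))
    p <- ps$D / ps$L
    as.vector(p[seq_len(nrow(m1)), nrow(m1) + seq_len(nrow(m2)),
                drop = FALSE])
  }
}

# core diversity quantities for a character matrix of haplotypes
.diversityCore <- function(m) {
  keep <- .retainedColumns(m)
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  n <- nrow(m)
  props <- .pairDiffProps(m)
  piPerBp <- if (L == 0L) 0 else mean(props, na.rm = TRUE)
  # segregating sites among retained columns, N as missing
  S <- 0L
  if (L > 0L) {
    for (col in seq_len(L)) {
      x <- m[, col]
      obs <- unique(x[x != "N"])
      if (length(obs) >= 2L) S <- S + 1L
    }
  }
  list(n = n, L = L, S = S, piPerBp = piPerBp, piTotal = piPerBp * L)
}

#' Nucleotide diversity (pi) per base pair
#'
#' Mean pairwise difference proportion among haplotypes:
#' \eqn{\pi = \sum_{i<j} d_{ij} / \binom{n}{2} / L} over the columns
#' retained after gap trimming, where missing (\code{N}) bases are dropped
#' pairwise with per-pair length normalization. No multiple-hit correction
#' is applied.
#'
#' @param aln a \code{\linkS4class{LocusAlignment}} or a character matrix of
#'   haplotypes (rows) by columns.
#' @param haplotypes optional character vector naming the haplotype subset
#'   (e.g. one population's haplotypes).
#' @return pi per bp (numeric scalar).
#' @export
setGeneric("nucleotideDiversity",
           function(aln, haplotypes = NULL) {
             standardGeneric("nucleotideDiversity")
           })

#' @rdname nucleotideDiversity
setMethod("nucleotideDiversity", "LocusAlignment",
  function(aln, haplotypes = NULL) {
    m <- .alnMatrix(aln, haplotypes)
    if (nrow(m) < 2L) stop("nucleotide diversity needs >= 2 haplotypes")
    .diversityCore(m)$piPerBp
  })

#' @rdname nucleotideDiversity
setMethod("nucleotideDiversity", "matrix",
  function(aln, haplotypes = NULL) {
    if (!is.null(haplotypes)) aln <- aln[haplotypes, , drop = FALSE]
    if (nrow(aln) < 2L) stop("nucleotide diversity needs >= 2 haplotypes")
    .diversityCore(aln)$piPerBp
  })

#' Watterson's theta per base pair
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes (>= 2).
#' @param length analyzed length in bp.
#' @return theta per bp.
#' @export
wattersonTheta <- function(S, n, length) {
  if (n < 2L) stop("wattersonTheta needs n >= 2")
  S / (.harmonic(n) * length)
}

# Tajima (1989) constants and D from (n, S, piTotal)
.tajimaComponents <- function(n, S, piTotal) {
  a1 <- .harmonic(n, 1)
  a2 <- .harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- NA_real_
  if (S >= 1L) {
    D <- (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  # support bounds of the beta approximation: D at the singleton-only and
  # maximally-even extremes of the frequency spectrum, in the large-S limit
  pihatMax <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- (pihatMax - 1 / a1) / sqrt(e2)
  structure(list(n = n, S = S, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2,
                 piTotal = piTotal, thetaW = S / a1,
                 D = D, Dmin = Dmin, Dmax = Dmax, p = NA_real_),
            class = "TajimaComponents")
}

#' @export
print.TajimaComponents <- function(x, ...) {
  cat("Tajima's D components: n =", x$n, ", S =", x$S, "\n")
  cat("  pi (per locus) =", signif(x$piTotal, 6),
      "; theta_W (per locus) =", signif(x$thetaW, 6), "\n")
  cat("  D =", signif(x$D, 6), "on [", signif(x$Dmin, 4), ",",
      signif(x$Dmax, 4), "], beta-test p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Tajima's D with its beta-distribution significance test
#'
#' \eqn{D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} over all segregating
#' sites, with the usual constants
#' \eqn{b_1=(n+1)/(3(n-1))}, \eqn{b_2=2(n^2+n+3)/(9n(n-1))},
#' \eqn{c_1=b_1-1/a_1}, \eqn{c_2=b_2-(n+2)/(a_1 n)+a_2/a_1^2},
#' \eqn{e_1=c_1/a_1}, \eqn{e_2=c_2/(a_1^2+a_2)}. The two-tailed p-value is
#' from the scaled beta approximation to the null distribution of D (see
#' [tajimaBetaPvalue()]). \code{S = 0} gives \code{D = NA}; \code{n < 4}
#' gives \code{NA} with a warning (the variance terms degenerate).
#'
#' @param x a \code{\linkS4class{LocusAlignment}}, or a 0/1 haplotype
#'   matrix (rows = haplotypes, columns = sites; no missing data), e.g.
#'   from [simulateCoalescentSample()].
#' @param haplotypes optional haplotype-name subset (alignment method).
#' @return A \code{"TajimaComponents"} list: n, S, the constants a1..e2,
#'   piTotal (per locus), thetaW (= S/a1), D, the beta support bounds
#'   Dmin/Dmax and the two-tailed p.
#' @export
setGeneric("tajimasD", function(x, haplotypes = NULL) {
  standardGeneric("tajimasD")
})

#' @rdname tajimasD
setMethod("tajimasD", "LocusAlignment", function(x, haplotypes = NULL) {
  m <- .alnMatrix(x, haplotypes)
  core <- .diversityCore(m)
  .tajimaFinish(core$n, core$S, core$piTotal)
})

#' @rdname tajimasD
setMethod("tajimasD", "matrix", function(x, haplotypes = NULL) {
  if (is.character(x)) {
    core <- .diversityCore(x)
    return(.tajimaFinish(core$n, core$S, core$piTotal))
  }
  n <- nrow(x)
  counts <- colSums(x)
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  piTotal <- if (n < 2) 0 else
    sum(counts[seg] * (n - counts[seg])) / choose(n, 2)
  .tajimaFinish(n, S, piTotal)
})

.tajimaFinish <- function(n, S, piTotal) {
  if (n < 4L) {
    warning("Tajima's D undefined for n < 4 (variance terms degenerate)",
            call. = FALSE)
    tc <- .tajimaComponents(max(n, 2L), S, piTotal)
    tc$D <- NA_real_
    return(tc)
  }
  tc <- .tajimaComponents(n, S, piTotal)
  if (!is.na(tc$D)) tc$p <- tajimaBetaPvalue(tc)
  tc
}

#' Two-tailed beta-distribution p-value for Tajima's D
#'
#' The null distribution of D is approximated by a beta distribution
#' rescaled onto the support \eqn{[D_{min}, D_{max}]} with shape parameters
#' chosen so the distribution has mean 0 and variance 1 on that support:
#' \eqn{\alpha = -(1 + D_{min} D_{max}) D_{max} / (D_{max} - D_{min})},
#' \eqn{\beta = (1 + D_{min} D_{max}) D_{min} / (D_{max} - D_{min})}.
#' The two-tailed p is \eqn{2 \min(F(D), 1 - F(D))}. Values of D outside
#' the support by more than 1e-9 are clamped with a warning.
#'
#' @param tc a \code{"TajimaComponents"} result with D defined.
#' @return two-tailed p-value.
#' @export
tajimaBetaPvalue <- function(tc) {
  D <- tc$D
  if (is.na(D)) stop("D is undefined; cannot compute beta p-value")
  a <- tc$Dmin
  b <- tc$Dmax
  if (D < a - 1e-9 || D > b + 1e-9) {
    warning("D = ", signif(D, 6), " outside beta support [",
            signif(a, 6), ", ", signif(b, 6), "]; clamped", call. = FALSE)
  }
  D <- min(max(D, a), b)
  shapeA <- -(1 + a * b) * b / (b - a)   # exponent of (b - D)
  shapeB <- (1 + a * b) * a / (b - a)    # exponent of (D - a)
  if (!(shapeA > 0 && shapeB > 0)) {
    warning("beta approximation unavailable (non-positive shape); ",
            "returning NA", call. = FALSE)
    return(NA_real_)
  }
  Fd <- stats::pbeta((D - a) / (b - a), shape1 = shapeB, shape2 = shapeA)
  2 * min(Fd, 1 - Fd)
}

#' Per-locus, per-population diversity summary
#'
#' @param aln a \code{\linkS4class{LocusAlignment}}.
#' @param popHaplotypes named list: population -> haplotype names.
#' @return data.frame with one row per population: locus_id, population,
#'   n_haplotypes, length_analyzed, S, pi_per_bp, theta_w_per_bp, D,
#'   D_pvalue.
#' @export
locusPopgenTable <- function(aln, popHaplotypes) {
  rows <- lapply(names(popHaplotypes), function(pop) {
    m <- .alnMatrix(aln, popHaplotypes[[pop]])
    core <- .diversityCore(m)
    tc <- suppressWarnings(.tajimaFinish(core$n, core$S, core$piTotal))
    data.frame(locus_id = locusId(aln), population = pop,
               n_haplotypes = core$n, length_analyzed = core$L,
               S = core$S, pi_per_bp = core$piPerBp,
               theta_w_per_bp = if (core$L > 0)
                 wattersonTheta(core$S, core$n, core$L) else 0,
               D = tc$D, D_pvalue = tc$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hudson's FST between two population samples
#'
#' \eqn{F_{ST} = 1 - H_w / H_b}, where \eqn{H_w} is the mean
#' within-population pairwise difference (by default the unweighted average
#' of the two populations' means) and \eqn{H_b} the mean pairwise
#' difference between populations. Computed on per-pair difference
#' proportions (pairwise deletion of missing bases). \eqn{H_b = 0} gives
#' \code{NA}; slightly negative estimates are reported unclamped.
#'
#' @param aln a \code{\linkS4class{LocusAlignment}}.
#' @param popAHaps,popBHaps haplotype names of the two populations (>= 2
#'   each).
#' @param popA,popB population labels for the output row.
#' @param weighted if \code{TRUE}, weight the two within-population means
#'   by their pair counts instead of averaging them unweighted.
#' @return One-row data.frame: locus_id, region, pop_a, pop_b, Hw, Hb, fst.
#' @export
hudsonFst <- function(aln, popAHaps, popBHaps,
                      popA = "pop_a", popB = "pop_b", weighted = FALSE) {
  if (length(popAHaps) < 2L || length(popBHaps) < 2L) {
    stop("hudsonFst needs >= 2 haplotypes per population")
  }
  m <- .alnMatrix(aln, c(popAHaps, popBHaps))
  keep <- .retainedColumns(m)
  m <- m[, keep, drop = FALSE]
  ma <- m[popAHaps, , drop = FALSE]
  mb <- m[popBHaps, , drop = FALSE]
  wa <- .pairDiffProps(ma)
  wb <- .pairDiffProps(mb)
  btw <- .pairDiffProps(ma, mb)
  Hw <- if (weighted) {
    mean(c(wa, wb), na.rm = TRUE)
  } else {
    (mean(wa, na.rm = TRUE) + mean(wb, na.rm = TRUE)) / 2
  }
  Hb <- mean(btw, na.rm = TRUE)
  fst <- if (Hb == 0) NA_real_ else 1 - Hw / Hb
  data.frame(locus_id = locusId(aln), region = region(aln),
             pop_a = popA, pop_b = popB, Hw = Hw, Hb = Hb, fst = fst,
             stringsAsFactors = FALSE)
}

#' Per-locus FST table across a list of alignments
#'
#' @param alignments list of \code{\linkS4class{LocusAlignment}} objects.
#' @param popAHaps,popBHaps haplotype names per population; haplotypes
#'   absent from a locus are dropped for that locus.
#' @param popA,popB population labels.
#' @param weighted see [hudsonFst()].
#' @return data.frame with one row per locus.
#' @export
fstTable <- function(alignments, popAHaps, popBHaps,
                     popA = "pop_a", popB = "pop_b", weighted = FALSE) {
  rows <- lapply(alignments, function(aln) {
    nm <- sequenceNames(aln)
    hudsonFst(aln, intersect(popAHaps, nm), intersect(popBHaps, nm),
              popA = popA, popB = popB, weighted = weighted)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
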