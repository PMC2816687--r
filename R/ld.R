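# Phase-free composite linkage disequilibrium (Burrows delta), computed
# from unphased diploid dosages without assuming HWE or known haplotypes.

# complete pairs of two dosage vectors as allele counts 0/1/2
.completeCounts <- function(di, dj) {
  ok <- !is.na(di) & !is.na(dj)
  list(x = 2 * di[ok], y = 2 * dj[ok], n = sum(ok))
}

#' Burrows composite disequilibrium Delta
#'
#' With \eqn{X, Y} the per-individual allele counts (0/1/2) at two sites,
#' \eqn{\Delta = \mathrm{cov}(X, Y) / 2} using the 1/n population
#' covariance; this equals the Burrows count formula
#' \eqn{\Delta = n_{AB}/n - 2 p_A p_B}.
#'
#' @param dosageI,dosageJ dosage vectors in \code{\{0, 0.5, 1\}} (NA
#'   allowed), aligned on individuals.
#' @return Delta, or \code{NA} if either site is monomorphic among the
#'   complete pairs (< 2 complete pairs is an error).
#' @export
compositeDelta <- function(dosageI, dosageJ) {
  cc <- .completeCounts(dosageI, dosageJ)
  if (cc$n < 2L) stop("compositeDelta needs >= 2 complete pairs")
  if (stats::sd(cc$x) == 0 || stats::sd(cc$y) == 0) return(NA_real_)
  (mean(cc$x * cc$y) - mean(cc$x) * mean(cc$y)) / 2
}

#' Composite r-squared
#'
#' The squared composite correlation
#' \eqn{r = \Delta / \sqrt{(p_A q_A + D_A)(p_B q_B + D_B)}}, where
#' \eqn{D_A = P_{AA} - p_A^2} is the within-locus Hardy-Weinberg
#' departure. This is identically the squared Pearson correlation of the
#' two dosage vectors, which is how it is computed; the uncorrected
#' denominator \eqn{p_A q_A p_B q_B} is not a bounded correlation and is
#' not offered.
#'
#' @inheritParams compositeDelta
#' @return r^2 in \code{[0, 1]}, or \code{NA} when monomorphic.
#' @export
compositeR2 <- function(dosageI, dosageJ) {
  cc <- .completeCounts(dosageI, dosageJ)
  if (cc$n < 2L) stop("compositeR2 needs >= 2 complete pairs")
  if (stats::sd(cc$x) == 0 || stats::sd(cc$y) == 0) return(NA_real_)
  stats::cor(cc$x, cc$y)^2
}

#' Pairwise composite LD over all site pairs
#'
#' Computes Delta and r^2 for every unordered pair of sites (upper
#' triangle). Pairs with fewer than \code{minN} individuals complete at
#' both sites are emitted with \code{NA} and reason
#' \code{"insufficient_n"} (the sample-size >= 20 rule); monomorphic pairs
#' get reason \code{"monomorphic"}. Distance is
#' \code{|position_i - position_j|} on the shared genomic axis, \code{NA}
#' when either locus has no offset (such pairs stay in the matrix but are
#' excluded from decay analysis).
#'
#' @param gm an informative-filtered \code{\linkS4class{GenotypeMatrix}}
#'   (see [filterInformative()]).
#' @param minN minimum individuals complete at both sites (default 20).
#' @return data.frame with one row per pair: site_i, site_j, locus_i,
#'   locus_j, pos_i, pos_j, distance, within_gene, n_used, delta, r2,
#'   reason, pair_class.
#' @export
ldMatrix <- function(gm, minN = 20) {
  d <- dosage(gm)
  si <- as.data.frame(siteInfo(gm))
  nS <- ncol(d)
  if (nS < 2L) stop("ldMatrix needs >= 2 sites")
  pos <- ifelse(is.na(si$position), NA_integer_, si$position)
  pairs <- utils::combn(nS, 2)
  nP <- ncol(pairs)
  out <- data.frame(
    site_i = colnames(d)[pairs[1, ]],
    site_j = colnames(d)[pairs[2, ]],
    locus_i = si$locus[pairs[1, ]],
    locus_j = si$locus[pairs[2, ]],
    pos_i = pos[pairs[1, ]],
    pos_j = pos[pairs[2, ]],
    distance = abs(pos[pairs[1, ]] - pos[pairs[2, ]]),
    within_gene = si$locus[pairs[1, ]] == si$locus[pairs[2, ]],
    n_used = integer(nP), delta = NA_real_, r2 = NA_real_,
    reason = NA_character_, pair_class = "other",
    stringsAsFactors = FALSE)
  for (k in seq_len(nP)) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    cc <- .completeCounts(d[, i], d[, j])
    out$n_used[k] <- cc$n
    if (cc$n < minN) {
      out$reason[k] <- "insufficient_n"
      next
    }
    if (stats::sd(cc$x) == 0 || stats::sd(cc$y) == 0) {
      out$reason[k] <- "monomorphic"
      next
    }
    out$delta[k] <- (mean(cc$x * cc$y) - mean(cc$x) * mean(cc$y)) / 2
    out$r2[k] <- stats::cor(cc$x, cc$y)^2
  }
  out
}

#' Square r-squared matrix for heatmap plotting
#'
#' @param records LD data.frame from [ldMatrix()].
#' @return symmetric numeric matrix of r^2 (diagonal 1), site names as
#'   dimnames.
#' @export
ldSquareMatrix <- function(records) {
  sites <- unique(c(records$site_i, records$site_j))
  m <- matrix(NA_real_, length(sites), length(sites),
              dimnames = list(sites, sites))
  diag(m) <- 1
  idx1 <- cbind(match(records$site_i, sites), match(records$site_j, sites))
  m[idx1] <- records$r2
  m[idx1[, 2:1, drop = FALSE]] <- records$r2
  m
}

#' LD decay with physical distance
#'
#' Mean r^2 per distance bin over pairs with a defined distance and a
#' computed r^2. Bins with no pairs are reported empty (mean \code{NA},
#' n = 0), not dropped.
#'
#' @param records LD data.frame from [ldMatrix()].
#' @param binEdges increasing numeric vector of bin edges in bp; bins are
#'   \code{[edge_k, edge_{k+1})}, the last bin closed.
#' @return data.frame: bin_lo, bin_hi, bin_mid, mean_r2, n_pairs.
#' @export
ldDecay <- function(records, binEdges) {
  use <- records[!is.na(records$distance) & !is.na(records$r2), ,
                 drop = FALSE]
  if (nrow(use) == 0L) {
    stop("no LD records with defined distance and r2")
  }
  nb <- length(binEdges) - 1L
  if (nb < 1L) stop("binEdges must define at least one bin")
  idx <- findInterval(use$distance, binEdges, rightmost.closed = TRUE)
  out <- data.frame(bin_lo = binEdges[-length(binEdges)],
                    bin_hi = binEdges[-1L])
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$mean_r2 <- vapply(seq_len(nb), function(k) {
    v <- use$r2[idx == k]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  out$n_pairs <- vapply(seq_len(nb), function(k) sum(idx == k), integer(1))
  out
}

#' Classify LD pairs by phenotype association of their sites
#'
#' Sets \code{pair_class = "both_associated"} for pairs whose two sites are
#' both significant in an association scan, \code{"other"} otherwise, and
#' adds per-site flags \code{sig_i}/\code{sig_j} so the "all sites",
#' "associated only" and "associated removed" subsets are derivable by
#' filtering. Sites without an association record are treated as not
#' significant, with a warning.
#'
#' @param records LD data.frame from [ldMatrix()].
#' @param assoc association data.frame from [associationScan()].
#' @return \code{records} with \code{pair_class}, \code{sig_i},
#'   \code{sig_j} filled in.
#' @export
partitionSitesByAssociation <- function(records, assoc) {
  if ("site" %in% colnames(assoc)) {
    key <- assoc$site
    keyI <- records$site_i
    keyJ <- records$site_j
  } else {
    key <- paste(assoc$locus, assoc$position)
    keyI <- paste(records$locus_i, records$pos_i)
    keyJ <- paste(records$locus_j, records$pos_j)
  }
  sig <- stats::setNames(assoc$significant, key)
  unknown <- setdiff(unique(c(keyI, keyJ)), key)
  if (length(unknown) > 0L) {
    warning(length(unknown), " LD site(s) without an association record; ",
            "classed as not associated", call. = FALSE)
  }
  sigI <- !is.na(sig[keyI]) & sig[keyI]
  sigJ <- !is.na(sig[keyJ]) & sig[keyJ]
  records$sig_i <- unname(sigI)
  records$sig_j <- unname(sigJ)
  records$pair_class <- ifelse(sigI & sigJ, "both_associated", "other")
  records
}

#' Remove every pair touching a phenotype-associated site
#'
#' Convenience filter for the "associated removed" decay analysis: keeps
#' only pairs where neither site is significant.
#'
#' @param records output of [partitionSitesByAssociation()].
#' @return The filtered data.frame.
#' @export
excludeAssociatedPairs <- function(records) {
  if (!all(c("sig_i", "sig_j") %in% colnames(records))) {
    stop("records must come from partitionSitesByAssociation()")
  }
  records[!records$sig_i & !records$sig_j, , drop = FALSE]
}
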