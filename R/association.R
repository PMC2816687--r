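#' Score colour-pattern phenotypes on the 0/0.5/1 scale
#'
#' Pure-race individuals receive 0.0 or 1.0 according to their race's fixed
#' allele; individuals flagged as hybrid heterozygotes (e.g. carriers of the
#' dominant red-band allele together with rayed-phenotype evidence, under
#' the rule that recombinants between the band and ray loci are rare) are
#' scored 0.5. Individuals with no declared phenotype stay missing and are
#' excluded from association testing only.
#'
#' @param samples sample data.frame from [readSampleTable()].
#' @param raceScores optional named vector mapping population to 0 or 1;
#'   when \code{NULL} the table's \code{phenotype_score} column is used.
#' @param hybridIds individual ids scored 0.5 by the dominance rule.
#' @return Named numeric vector of scores in \code{\{0, 0.5, 1, NA\}}.
#' @export
scorePhenotypes <- function(samples, raceScores = NULL,
                            hybridIds = character(0)) {
  if (is.null(raceScores)) {
    scores <- samples$phenotype_score
  } else {
    scores <- unname(raceScores[samples$population])
  }
  scores[samples$individual_id %in% hybridIds] <- 0.5
  bad <- !is.na(scores) & !(scores %in% c(0, 0.5, 1))
  if (any(bad)) {
    stop("invalid phenotype score for: ",
         paste(samples$individual_id[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(scores, samples$individual_id)
}

#' Chi-squared linear trend test of dosage against phenotype
#'
#' Score-test form of the Armitage trend test:
#' \eqn{\chi^2 = n r^2} with 1 df, where \eqn{r} is the Pearson correlation
#' of genotype dosage and phenotype score over the complete pairs, assuming
#' a linear genotype-phenotype relationship. Individuals missing either
#' value are dropped pairwise. Zero variance in either vector yields
#' \code{NA} with reason \code{"monomorphic"}.
#'
#' @param dosageVec dosage values in \code{\{0, 0.5, 1\}} (NA allowed).
#' @param phenotype phenotype scores in \code{\{0, 0.5, 1\}} (NA allowed).
#' @return list: \code{nUsed}, \code{chi2}, \code{p} (upper tail, 1 df),
#'   \code{negLog10P}, \code{reason} (\code{NA} or \code{"monomorphic"}).
#' @export
trendTest <- function(dosageVec, phenotype) {
  ok <- !is.na(dosageVec) & !is.na(phenotype)
  x <- dosageVec[ok]
  y <- phenotype[ok]
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(nUsed = n, chi2 = NA_real_, p = NA_real_,
                negLog10P = NA_real_, reason = "monomorphic"))
  }
  r <- stats::cor(x, y)
  chi2 <- n * r^2
  logp <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(nUsed = n, chi2 = chi2, p = exp(logp),
       negLog10P = -logp / log(10), reason = NA_character_)
}

#' Bonferroni significance cutoff on the -log10 scale
#'
#' \eqn{-\log_{10}(\alpha / m)}; with \eqn{\alpha = 0.05} over 866 sites
#' this is 4.24 (2 dp).
#'
#' @param alpha family-wise error rate in (0, 1].
#' @param mSites number of tests (>= 1).
#' @return cutoff on the -log10(p) scale.
#' @export
bonferroniThreshold <- function(alpha, mSites) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  if (!is.numeric(mSites) || mSites < 1) {
    stop("mSites must be a positive integer")
  }
  -log10(alpha / mSites)
}

#' Genome-scan of genotype-by-phenotype trend tests
#'
#' Runs [trendTest()] at every site of a genotype matrix and marks
#' significance against a Bonferroni cutoff. By default the correction uses
#' the number of testable sites in this scan; \code{mTotal} overrides it to
#' correct jointly across several scans (e.g. all 866 sites of a combined
#' study, giving cutoff 4.24 regardless of this scan's size). Significance
#' uses strict \code{>} against the -log10 cutoff.
#'
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @param phenotypes named phenotype-score vector (see
#'   [scorePhenotypes()]); aligned to individuals by name.
#' @param alpha family-wise error rate (default 0.05).
#' @param mTotal optional total number of tests for the joint correction.
#' @return data.frame sorted by (locus, position): site, locus, position
#'   (1-based), n_used, chi2, p, neg_log10_p, significant, reason; the
#'   cutoff and m used are attached as attributes \code{"cutoff"} and
#'   \code{"m"}.
#' @export
associationScan <- function(gm, phenotypes, alpha = 0.05, mTotal = NULL) {
  d <- dosage(gm)
  si <- as.data.frame(siteInfo(gm))
  ph <- phenotypes[rownames(d)]
  res <- lapply(seq_len(ncol(d)), function(j) trendTest(d[, j], ph))
  out <- data.frame(
    site = colnames(d),
    locus = si$locus,
    position = ifelse(is.na(si$position), si$column + 1L, si$position),
    n_used = vapply(res, `[[`, integer(1), "nUsed"),
    chi2 = vapply(res, `[[`, numeric(1), "chi2"),
    p = vapply(res, `[[`, numeric(1), "p"),
    neg_log10_p = vapply(res, `[[`, numeric(1), "negLog10P"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  testable <- sum(!is.na(out$chi2))
  if (testable == 0L) {
    warning("no testable sites in association scan", call. = FALSE)
    out$significant <- logical(nrow(out))
    attr(out, "cutoff") <- NA_real_
    attr(out, "m") <- 0L
    return(out[order(out$locus, out$position), , drop = FALSE])
  }
  m <- mTotal %||% testable
  cutoff <- bonferroniThreshold(alpha, m)
  out$significant <- !is.na(out$neg_log10_p) & out$neg_log10_p > cutoff
  out <- out[order(out$locus, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "m") <- m
  out
}
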