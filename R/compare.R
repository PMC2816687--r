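#' Mann-Whitney U test with small-sample exact enumeration
#'
#' U is computed from midrank sums: \eqn{U = R_1 - n_1(n_1+1)/2}. When
#' \eqn{n_1 + n_2 \le 14} the p-value is exact, by full enumeration of all
#' \eqn{\binom{n_1+n_2}{n_1}} group labelings of the pooled midranks
#' (ties handled naturally); otherwise the normal approximation with tie
#' correction and continuity correction is used. Two-sided p-values sum
#' both tails as extreme as the observed \eqn{|U - n_1 n_2 / 2|}.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (x tends larger) or \code{"less"}.
#' @param exactLimit pooled size at or below which enumeration is used.
#' @return list: \code{U} (for x), \code{p}, \code{exact} (logical),
#'   \code{n1}, \code{n2}.
#' @export
mannWhitneyU <- function(x, y, alternative = c("two.sided", "greater",
                                               "less"),
                         exactLimit = 14L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("mannWhitneyU needs non-empty vectors")
  }
  if (anyNA(x) || anyNA(y)) stop("mannWhitneyU does not accept NA values")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- 1e-9
  if (N <= exactLimit) {
    subsets <- utils::combn(N, n1)
    Uvals <- colSums(matrix(rk[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Uvals - mu) >= abs(U - mu) - eps),
      greater = mean(Uvals >= U - eps),
      less = mean(Uvals <= U + eps))
    return(list(U = U, p = p, exact = TRUE, n1 = n1, n2 = n2))
  }
  tie <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, exact = FALSE, n1 = n1, n2 = n2))
  }
  sigma <- sqrt(sigma2)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(max(abs(U - mu) - 0.5, 0) / sigma,
                                        lower.tail = FALSE)),
    greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((U - mu + 0.5) / sigma))
  list(U = U, p = p, exact = FALSE, n1 = n1, n2 = n2)
}

#' Contrast FST at colour-pattern-linked versus unlinked loci
#'
#' Splits a per-locus FST table into wing-pattern-linked loci (regions
#' \code{HmYb}/\code{HmB}) and unlinked loci, reports the per-class mean
#' and standard deviation (n - 1 denominator) in the style of a
#' mean-plus-sd comparison table, and tests the difference with a
#' Mann-Whitney U test (two-sided by default). \code{NA} FST values are
#' excluded and counted.
#'
#' @param fstTable data.frame with columns \code{region} and \code{fst}
#'   (e.g. from [fstTable()]).
#' @param linkedRegions region labels treated as linked.
#' @param alternative passed to [mannWhitneyU()].
#' @return One-row data.frame: n_linked, mean_linked, sd_linked,
#'   n_unlinked, mean_unlinked, sd_unlinked, U, p, exact, n_na_excluded.
#' @export
compareFstClasses <- function(fstTable, linkedRegions = c("HmYb", "HmB"),
                              alternative = "two.sided") {
  ok <- !is.na(fstTable$fst)
  nNA <- sum(!ok)
  ft <- fstTable[ok, , drop = FALSE]
  linked <- ft$fst[ft$region %in% linkedRegions]
  unlinked <- ft$fst[!ft$region %in% linkedRegions]
  if (length(linked) == 0L) stop("no linked loci with defined FST")
  if (length(unlinked) == 0L) stop("no unlinked loci with defined FST")
  mw <- mannWhitneyU(linked, unlinked, alternative = alternative)
  data.frame(
    n_linked = length(linked),
    mean_linked = mean(linked),
    sd_linked = if (length(linked) > 1L) stats::sd(linked) else NA_real_,
    n_unlinked = length(unlinked),
    mean_unlinked = mean(unlinked),
    sd_unlinked = if (length(unlinked) > 1L) stats::sd(unlinked)
                  else NA_real_,
    U = mw$U, p = mw$p, exact = mw$exact, n_na_excluded = nNA,
    stringsAsFactors = FALSE)
}
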