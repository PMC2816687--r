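#' Read a qPCR Ct table
#'
#' Comma-separated table with columns \code{sample_id}, \code{gene},
#' \code{ct_target}, \code{ct_reference} plus any categorical covariate
#' columns (race, stage, wing, segment, individual, ...). Ct values must be
#' finite and positive. Technical replicates appear as repeated
#' sample/gene rows and can be averaged with [averageReplicates()].
#'
#' @param path path to the CSV file.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct_target", "ct_reference")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L) {
    stop("Ct table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  df
}

#' Relative expression from a delta-Ct
#'
#' \eqn{\mathrm{expression} = E^{(Ct_{ref} - Ct_{target})}} with
#' amplification efficiency \eqn{E} fixed at 2 by default (classic
#' delta-Ct, target normalized to a housekeeping reference from the same
#' cDNA synthesis).
#'
#' @param ctTarget,ctReference threshold cycles (vectors recycle).
#' @param efficiency per-cycle amplification factor (default 2).
#' @return expression ratio(s).
#' @export
relativeExpression <- function(ctTarget, ctReference, efficiency = 2) {
  if (missing(ctReference) || is.null(ctReference) || anyNA(ctReference)) {
    stop("reference Ct is required for normalization")
  }
  if (anyNA(ctTarget)) stop("target Ct contains missing values")
  efficiency^(ctReference - ctTarget)
}

#' Average technical replicates
#'
#' Computes relative expression per row, checks that the replicate spread
#' (max - min) within each sample-gene group is below \code{maxSpread} on
#' the relative-expression scale (the replicate-consistency criterion),
#' then averages replicates. Covariate columns must be constant within a
#' group.
#'
#' @param ct Ct data.frame from [readCtTable()].
#' @param efficiency passed to [relativeExpression()].
#' @param maxSpread allowed replicate spread (default 0.05).
#' @return data.frame with one row per sample-gene combination and an
#'   \code{expression} column.
#' @export
averageReplicates <- function(ct, efficiency = 2, maxSpread = 0.05) {
  ct$expression <- relativeExpression(ct$ct_target, ct$ct_reference,
                                      efficiency)
  keyCols <- c("sample_id", "gene")
  covCols <- setdiff(colnames(ct),
                     c(keyCols, "ct_target", "ct_reference", "expression"))
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  rows <- lapply(split(ct, key), function(g) {
    spread <- max(g$expression) - min(g$expression)
    if (spread >= maxSpread) {
      warning("replicate spread ", signif(spread, 3), " >= ", maxSpread,
              " for sample ", g$sample_id[1], ", gene ", g$gene[1],
              call. = FALSE)
    }
    out <- g[1, c(keyCols, covCols), drop = FALSE]
    out$expression <- mean(g$expression)
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Fold change between groups (geometric means)
#'
#' \eqn{\mathrm{fold} = \mathrm{GM}(a) / \mathrm{GM}(b)}: expression
#' ratios are multiplicative, so the geometric (not arithmetic) mean is
#' used.
#'
#' @param expressions positive expression values.
#' @param groupLabels group label per value.
#' @param groupA,groupB the two group labels to compare.
#' @return fold change of \code{groupA} over \code{groupB}.
#' @export
groupFoldChange <- function(expressions, groupLabels, groupA, groupB) {
  if (any(expressions <= 0)) {
    stop("expressions must be strictly positive")
  }
  a <- expressions[groupLabels == groupA]
  b <- expressions[groupLabels == groupB]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty")
  }
  exp(mean(log(a)) - mean(log(b)))
}

#' Bayesian model averaging over covariate subsets
#'
#' Enumerates all \eqn{2^K} subsets of the candidate covariates, fits each
#' by ordinary least squares on log2 expression, weights models by
#' \eqn{\exp(-\mathrm{BIC}/2)} with
#' \eqn{\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n} (k = number of
#' regression coefficients including the intercept), and reports the
#' posterior inclusion probability \eqn{\Pr(\beta \neq 0)} of each
#' covariate on the percent scale, plus model-averaged coefficients.
#' Rank-deficient designs are skipped with a warning and the weights
#' renormalized.
#'
#' @param logExpressions numeric response (log2 relative expression).
#' @param covariateTable data.frame of categorical covariates, one row per
#'   observation.
#' @param candidates covariate names to enumerate (default: all columns).
#' @return A \code{\linkS4class{BmaSummary}}.
#' @export
bmaInclusion <- function(logExpressions, covariateTable,
                         candidates = colnames(covariateTable)) {
  y <- as.numeric(logExpressions)
  n <- length(y)
  if (nrow(covariateTable) != n) {
    stop("covariateTable rows must match the response length")
  }
  if (length(candidates) < 1L) stop("need at least one candidate covariate")
  covs <- covariateTable[, candidates, drop = FALSE]
  covs[] <- lapply(covs, function(v) factor(as.character(v)))
  X <- stats::model.matrix(~ ., data = covs)
  term <- attr(X, "assign")           # 0 = intercept, 1..K = candidates
  K <- length(candidates)
  if (n <= ncol(X)) {
    stop("full model not identifiable: n = ", n, " <= ", ncol(X),
         " parameters")
  }
  nModels <- 2^K
  bic <- rep(NA_real_, nModels)
  kPar <- integer(nModels)
  rss <- rep(NA_real_, nModels)
  coefList <- vector("list", nModels)
  subsetStr <- character(nModels)
  contains <- matrix(FALSE, nModels, K, dimnames = list(NULL, candidates))
  skipped <- 0L
  for (mIdx in seq_len(nModels)) {
    inSet <- as.logical(bitwAnd(mIdx - 1L, 2L^(seq_len(K) - 1L)) > 0L)
    contains[mIdx, ] <- inSet
    subsetStr[mIdx] <- if (any(inSet)) {
      paste(candidates[inSet], collapse = "+")
    } else "(intercept)"
    cols <- term == 0L | term %in% which(inSet)
    Xm <- X[, cols, drop = FALSE]
    fit <- stats::lm.fit(Xm, y)
    if (fit$rank < ncol(Xm)) {
      warning("rank-deficient design for model '", subsetStr[mIdx],
              "'; skipped", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    r2 <- sum(fit$residuals^2)
    kPar[mIdx] <- ncol(Xm)
    rss[mIdx] <- r2
    bic[mIdx] <- if (r2 < 1e-300) -Inf else
      n * log(r2 / n) + ncol(Xm) * log(n)
    cf <- fit$coefficients
    coefList[[mIdx]] <- cf
  }
  ok <- !is.na(bic)
  if (!any(ok)) stop("no model could be fitted")
  w <- rep(0, nModels)
  if (any(is.infinite(bic[ok]) & bic[ok] < 0)) {
    perfect <- ok & is.infinite(bic) & bic < 0
    w[perfect] <- 1 / sum(perfect)
  } else {
    rel <- exp(-(bic[ok] - min(bic[ok])) / 2)
    w[ok] <- rel / sum(rel)
  }
  inclusion <- 100 * as.numeric(t(w) %*% contains)
  names(inclusion) <- candidates
  avg <- stats::setNames(rep(0, ncol(X)), colnames(X))
  for (mIdx in which(w > 0)) {
    cf <- coefList[[mIdx]]
    avg[names(cf)] <- avg[names(cf)] + w[mIdx] * cf
  }
  models <- data.frame(subset = subsetStr, k = kPar, rss = rss, bic = bic,
                       weight = w, stringsAsFactors = FALSE)[ok, ]
  rownames(models) <- NULL
  new("BmaSummary", inclusion = inclusion, coefficients = avg,
      models = models, n = as.integer(n))
}

#' qPCR expression analysis pipeline
#'
#' Averages technical replicates, takes log2 relative expression for one
#' gene, and runs [bmaInclusion()] over the requested covariates. The
#' between-segments and between-races experiments are two covariate
#' configurations of this same call (e.g. \code{c("stage", "segment")} vs
#' \code{c("race", "stage", "wing")}).
#'
#' @param ct Ct data.frame from [readCtTable()].
#' @param gene gene to analyze.
#' @param candidates covariate column names.
#' @param efficiency amplification efficiency.
#' @return list: \code{bma} (a \code{\linkS4class{BmaSummary}}) and
#'   \code{data} (the averaged per-sample table with \code{expression}).
#' @export
qpcrAnalysis <- function(ct, gene, candidates, efficiency = 2) {
  avg <- averageReplicates(ct[ct$gene == gene, , drop = FALSE],
                           efficiency = efficiency)
  bma <- bmaInclusion(log2(avg$expression),
                      avg[, candidates, drop = FALSE],
                      candidates = candidates)
  list(bma = bma, data = avg)
}
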