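#' Aligned haplotype sequences for one locus
#'
#' A \code{LocusAlignment} holds the aligned haplotype sequences of one
#' sequenced locus (two haplotypes per diploid individual), together with its
#' region label (\code{"HmYb"}, \code{"HmB"} or \code{"unlinked"}) and, when
#' known, the genomic offset placing alignment column 1 on a shared
#' coordinate axis (1-based bp). Columns are addressed 0-based internally;
#' all written output is 1-based.
#'
#' @slot locusId single locus identifier.
#' @slot region one of \code{"HmYb"}, \code{"HmB"}, \code{"unlinked"}.
#' @slot genomicOffset integer bp position of column 1 on the shared axis,
#'   or \code{NA} when the locus is not placed.
#' @slot sequences a \code{\link[Biostrings]{DNAStringSet}} of equal-width
#'   sequences over \code{A,C,G,T,N,-}; names are haplotype names, unique
#'   within the locus.
#'
#' @seealso [readLocusAlignments()], [callVariableSites()],
#'   [nucleotideDiversity()], [tajimasD()], [hudsonFst()]
#' @export
setClass("LocusAlignment",
  slots = c(
    locusId = "character",
    region = "character",
    genomicOffset = "integer",
    sequences = "DNAStringSet"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L || is.na(object@locusId) ||
      !nzchar(object@locusId)) {
    msg <- c(msg, "locusId must be a single non-empty string")
  }
  if (length(object@region) != 1L || !object@region %in% .regionLevels) {
    msg <- c(msg, paste0("region must be one of ",
                         paste(.regionLevels, collapse = ", ")))
  }
  if (length(object@genomicOffset) != 1L) {
    msg <- c(msg, "genomicOffset must be a single integer (NA allowed)")
  }
  n <- length(object@sequences)
  if (n < 2L) msg <- c(msg, "alignment needs >= 2 sequences")
  if (n >= 1L) {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) != 1L) {
      msg <- c(msg, "ragged alignment: sequences have unequal lengths")
    }
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
      msg <- c(msg, "sequence names must be present and unique")
    }
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct a LocusAlignment
#'
#' @param locusId locus identifier.
#' @param sequences named character vector or
#'   \code{\link[Biostrings]{DNAStringSet}} of equal-length aligned
#'   haplotype sequences. Ambiguity codes other than \code{N} are collapsed
#'   to \code{N}.
#' @param region region label, one of \code{"HmYb"}, \code{"HmB"},
#'   \code{"unlinked"}.
#' @param genomicOffset 1-based bp coordinate of alignment column 1 on the
#'   shared genomic axis, or \code{NA}.
#' @return A \code{\linkS4class{LocusAlignment}}.
#' @examples
#' aln <- LocusAlignment("locus1",
#'   c(h1 = "ACGT", h2 = "ACGT", h3 = "ACTT", h4 = "ACTT"),
#'   region = "HmB", genomicOffset = 1000L)
#' alignmentLength(aln)
#' @export
LocusAlignment <- function(locusId, sequences, region = "unlinked",
                           genomicOffset = NA_integer_) {
  if (is.character(sequences)) {
    sequences <- .cleanSequences(sequences)
  }
  new("LocusAlignment",
      locusId = as.character(locusId),
      region = as.character(region),
      genomicOffset = as.integer(genomicOffset),
      sequences = sequences)
}

# uppercase and collapse anything outside the alphabet to N
.cleanSequences <- function(x) {
  chr <- toupper(as.character(x))
  chr <- gsub("[^ACGTN-]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Dosage-coded genotype matrix
#'
#' Individuals-by-sites matrix of minor-allele dosage in
#' \code{\{0, 0.5, 1\}} (\code{NA} = missing), with per-site metadata:
#' locus, 0-based alignment column, 1-based global position (\code{NA} when
#' the locus has no genomic offset), allele labels
#' (\code{major/minor-class}), minor-class frequency (\code{maf}) and the
#' number of called haplotypes.
#'
#' @slot dosage numeric matrix, rows = individuals, columns = sites.
#' @slot siteInfo a \code{\link[S4Vectors]{DataFrame}} with one row per
#'   site: \code{locus}, \code{column}, \code{position}, \code{alleles},
#'   \code{maf}, \code{nCalled}, \code{condensed}, \code{condensedRule}.
#'
#' @seealso [buildGenotypeMatrix()], [filterInformative()],
#'   [associationScan()], [ldMatrix()]
#' @export
setClass("GenotypeMatrix",
  slots = c(
    dosage = "matrix",
    siteInfo = "DataFrame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  si <- object@siteInfo
  need <- c("locus", "column", "position", "alleles", "maf", "nCalled")
  if (!all(need %in% colnames(si))) {
    msg <- c(msg, paste0("siteInfo must contain columns: ",
                         paste(need, collapse = ", ")))
  }
  if (nrow(si) != ncol(d)) {
    msg <- c(msg, "siteInfo rows must match dosage columns")
  }
  if (ncol(d) > 0L && nrow(d) > 0L) {
    v <- d[!is.na(d)]
    if (length(v) > 0L && !all(v %in% c(0, 0.5, 1))) {
      msg <- c(msg, "dosage entries must be in {0, 0.5, 1} or NA")
    }
  }
  if (is.null(rownames(d))) msg <- c(msg, "dosage must have individual ids as rownames")
  if (length(msg) > 0L) msg else TRUE
})

#' Summary of a Bayesian-model-averaging fit
#'
#' Result of enumerating all covariate subsets of a linear model for
#' log2 expression, weighting each by its BIC, and averaging.
#'
#' @slot inclusion per-covariate posterior inclusion probability
#'   \eqn{\Pr(\beta \neq 0)}, on the percent scale.
#' @slot coefficients model-averaged regression coefficients (design-matrix
#'   columns; a coefficient contributes 0 from models that exclude it).
#' @slot models data.frame with one row per fitted model: covariate subset,
#'   parameter count \code{k}, \code{rss}, \code{bic}, \code{weight}.
#' @slot n number of observations.
#'
#' @seealso [bmaInclusion()]
#' @export
setClass("BmaSummary",
  slots = c(
    inclusion = "numeric",
    coefficients = "numeric",
    models = "data.frame",
    n = "integer"
  )
)

setValidity("BmaSummary", function(object) {
  msg <- character()
  if (any(object@inclusion < -1e-9 | object@inclusion > 100 + 1e-9)) {
    msg <- c(msg, "inclusion probabilities must lie in [0, 100]")
  }
  if (nrow(object@models) > 0L &&
      abs(sum(object@models$weight) - 1) > 1e-8) {
    msg <- c(msg, "model weights must sum to 1")
  }
  if (length(msg) > 0L) msg else TRUE
})
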