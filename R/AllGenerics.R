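# accessor generics and show methods

#' @rdname LocusAlignment-class
#' @param object,x a \code{LocusAlignment} or \code{GenotypeMatrix}.
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("genomicOffset", function(x) standardGeneric("genomicOffset"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("sequenceNames", function(x) standardGeneric("sequenceNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname BmaSummary-class
#' @export
setGeneric("inclusionProbabilities",
           function(x) standardGeneric("inclusionProbabilities"))

#' @rdname BmaSummary-class
#' @export
setGeneric("averagedCoefficients",
           function(x) standardGeneric("averagedCoefficients"))

#' @rdname BmaSummary-class
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))

#' @rdname LocusAlignment-class
setMethod("locusId", "LocusAlignment", function(x) x@locusId)

#' @rdname LocusAlignment-class
setMethod("region", "LocusAlignment", function(x) x@region)

#' @rdname LocusAlignment-class
setMethod("genomicOffset", "LocusAlignment", function(x) x@genomicOffset)

#' @rdname LocusAlignment-class
setMethod("alignmentLength", "LocusAlignment", function(x) {
  unique(Biostrings::width(x@sequences))[1]
})

#' @rdname LocusAlignment-class
setMethod("sequenceNames", "LocusAlignment", function(x) names(x@sequences))

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@locusId, "' (", object@region, ")\n",
      sep = "")
  cat("  ", length(object@sequences), " haplotypes x ",
      alignmentLength(object), " columns", sep = "")
  if (!is.na(object@genomicOffset)) {
    cat("; offset ", object@genomicOffset, " bp", sep = "")
  }
  cat("\n")
})

#' @rdname GenotypeMatrix-class
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
setMethod("siteInfo", "GenotypeMatrix", function(x) x@siteInfo)

#' @rdname GenotypeMatrix-class
setMethod("individuals", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname GenotypeMatrix-class
setMethod("nSites", "GenotypeMatrix", function(x) ncol(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object@dosage), " individuals x ",
      ncol(object@dosage), " sites\n", sep = "")
  if (ncol(object@dosage) > 0L) {
    loci <- unique(object@siteInfo$locus)
    cat("  loci: ", paste(utils::head(loci, 6), collapse = ", "),
        if (length(loci) > 6) ", ...", "\n", sep = "")
    cat("  maf range: ",
        paste(signif(range(object@siteInfo$maf), 3), collapse = " - "),
        "\n", sep = "")
  }
  nmiss <- sum(is.na(object@dosage))
  if (nmiss > 0L) cat("  missing entries: ", nmiss, "\n", sep = "")
})

#' @rdname BmaSummary-class
setMethod("inclusionProbabilities", "BmaSummary", function(x) x@inclusion)

#' @rdname BmaSummary-class
setMethod("averagedCoefficients", "BmaSummary", function(x) x@coefficients)

#' @rdname BmaSummary-class
setMethod("modelTable", "BmaSummary", function(x) x@models)

setMethod("show", "BmaSummary", function(object) {
  cat("BmaSummary over", nrow(object@models), "models, n =",
      object@n, "\n")
  cat("Posterior inclusion probabilities Pr(beta != 0), percent:\n")
  print(round(object@inclusion, 1))
})
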