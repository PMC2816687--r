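#' Call variable sites from a locus alignment
#'
#' Alignment columns containing any gap character \code{-} are excluded
#' entirely (indel regions are trimmed before analysis); \code{N} is treated
#' as missing. A retained column is a variant site when at least two
#' distinct non-missing bases are each observed at least once. Alleles are
#' ordered by descending frequency among non-missing calls, ties broken
#' alphabetically (so at maf = 0.5 the alphabetically later allele is the
#' minor allele).
#'
#' @param aln a \code{\linkS4class{LocusAlignment}}.
#' @return A list of variant-site records (class \code{"VariantSite"}), each
#'   with fields \code{locusId}, \code{region}, \code{column} (0-based),
#'   \code{position} (1-based global bp, \code{NA} without an offset),
#'   \code{alleles}, \code{counts}, \code{freqs}, \code{hapCalls} (named allele indices,
#'   \code{NA} = missing), \code{maf} (frequency of the non-major class),
#'   \code{nCalled}, \code{condensed}, \code{condensedRule}.
#' @export
callVariableSites <- function(aln) {
  m <- .alnMatrix(aln)
  keep <- .retainedColumns(m)
  off <- genomicOffset(aln)
  sites <- list()
  for (col in keep) {
    x <- m[, col]
    obs <- x[x != "N"]
    if (length(obs) == 0L) next
    tab <- table(obs)
    if (length(tab) < 2L) next
    ord <- order(-as.numeric(tab), names(tab))
    alleles <- names(tab)[ord]
    counts <- as.integer(tab)[ord]
    freqs <- counts / sum(counts)
    calls <- match(x, alleles)          # N -> NA
    names(calls) <- rownames(m)
    site <- structure(list(
      locusId = locusId(aln),
      region = region(aln),
      column = col - 1L,
      position = if (is.na(off)) NA_integer_ else off + (col - 1L),
      alleles = alleles,
      counts = counts,
      freqs = freqs,
      hapCalls = calls,
      # from counts, so threshold comparisons are float-exact
      maf = sum(counts[-1L]) / sum(counts),
      nCalled = sum(counts),
      condensed = FALSE,
      condensedRule = NA_character_
    ), class = "VariantSite")
    sites[[length(sites) + 1L]] <- site
  }
  sites
}

#' Condense a multi-allelic site to a biallelic SNP
#'
#' Sites with more than two alleles whose rarest allele has frequency below
#' \code{mafThreshold} have all non-major alleles merged into a single
#' minor class (the rule used for LD informativeness). Multi-allelic sites
#' whose minor alleles are all at or above the threshold are still
#' condensed major-vs-rest, but flagged with
#' \code{condensedRule = "major-vs-rest"} so they can be excluded.
#' Biallelic sites are returned unchanged. The major allele and the total
#' frequency mass are never altered.
#'
#' @param site a \code{"VariantSite"} record from [callVariableSites()].
#' @param mafThreshold rare-allele frequency below which minors are merged
#'   under the standard rule (default 0.05).
#' @return The (possibly condensed) \code{"VariantSite"}.
#' @export
condenseMultiallelic <- function(site, mafThreshold = 0.05) {
  k <- length(site$alleles)
  if (k <= 2L) return(site)
  rule <- if (min(site$freqs) < mafThreshold) "rare-minor" else "major-vs-rest"
  minorLabel <- paste(site$alleles[-1L], collapse = "/")
  site$alleles <- c(site$alleles[1L], minorLabel)
  site$counts <- c(site$counts[1L], sum(site$counts[-1L]))
  site$freqs <- site$counts / sum(site$counts)
  site$hapCalls[!is.na(site$hapCalls) & site$hapCalls > 1L] <- 2L
  site$maf <- site$counts[2L] / sum(site$counts)
  site$condensed <- TRUE
  site$condensedRule <- rule
  site
}

#' Build the dosage genotype matrix
#'
#' Converts per-haplotype allele calls into per-individual minor-allele
#' dosage \code{(copies of minor allele)/2} in \code{\{0, 0.5, 1\}}. Sites
#' still multi-allelic are condensed first with [condenseMultiallelic()].
#' If either haplotype call is missing at a site the dosage entry is
#' missing. Individuals without both haplotypes present among a site's
#' calls are excluded from that site with a warning.
#'
#' @param sites list of \code{"VariantSite"} records (possibly from several
#'   loci; haplotype names must be globally unique across individuals).
#' @param samples sample data.frame from [readSampleTable()].
#' @param mafThreshold passed to [condenseMultiallelic()].
#' @return A \code{\linkS4class{GenotypeMatrix}}.
#' @export
buildGenotypeMatrix <- function(sites, samples, mafThreshold = 0.05) {
  sites <- lapply(sites, condenseMultiallelic, mafThreshold = mafThreshold)
  nInd <- nrow(samples)
  nS <- length(sites)
  d <- matrix(NA_real_, nrow = nInd, ncol = nS,
              dimnames = list(samples$individual_id, NULL))
  info <- data.frame(locus = character(nS), column = integer(nS),
                     position = integer(nS), alleles = character(nS),
                     maf = numeric(nS), nCalled = integer(nS),
                     condensed = logical(nS),
                     condensedRule = character(nS),
                     stringsAsFactors = FALSE)
  dropped <- 0L
  for (j in seq_len(nS)) {
    s <- sites[[j]]
    calls <- s$hapCalls
    h1 <- calls[samples$hap1]
    h2 <- calls[samples$hap2]
    present <- samples$hap1 %in% names(calls) & samples$hap2 %in% names(calls)
    dropped <- dropped + sum(!present)
    dos <- ((h1 == 2L) + (h2 == 2L)) / 2
    dos[!present] <- NA_real_
    d[, j] <- dos
    info$locus[j] <- s$locusId
    info$column[j] <- s$column
    info$position[j] <- s$position
    info$alleles[j] <- paste(s$alleles, collapse = "|")
    info$maf[j] <- s$maf
    info$nCalled[j] <- s$nCalled
    info$condensed[j] <- s$condensed
    info$condensedRule[j] <- s$condensedRule
  }
  if (dropped > 0L) {
    warning(dropped, " individual-site entries dropped: haplotype not ",
            "called at locus", call. = FALSE)
  }
  colnames(d) <- paste0(info$locus, ":",
                        ifelse(is.na(info$position),
                               paste0("c", info$column + 1L),
                               info$position))
  new("GenotypeMatrix", dosage = d, siteInfo = S4Vectors::DataFrame(info))
}

#' Filter sites informative for LD analysis
#'
#' Retains sites whose minor-class frequency is strictly greater than
#' \code{mafThreshold} (rare-allele frequency > 0.05 by default), preserving
#' site order.
#'
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @param mafThreshold minimum (exclusive) minor-allele frequency.
#' @return The filtered \code{\linkS4class{GenotypeMatrix}}.
#' @export
filterInformative <- function(gm, mafThreshold = 0.05) {
  keep <- which(gm@siteInfo$maf > mafThreshold)
  new("GenotypeMatrix",
      dosage = gm@dosage[, keep, drop = FALSE],
      siteInfo = gm@siteInfo[keep, , drop = FALSE])
}

#' One-call pipeline from alignments to a genotype matrix
#'
#' Calls variable sites on each alignment, condenses multi-allelic sites,
#' and assembles the combined dosage matrix over all loci for the supplied
#' samples. Individuals missing from a locus are handled per locus via
#' [matchSamplesToAlignment()] semantics (their entries are missing at that
#' locus's sites).
#'
#' @param alignments list of \code{\linkS4class{LocusAlignment}} objects.
#' @param samples sample data.frame.
#' @param mafThreshold condensation threshold.
#' @return A \code{\linkS4class{GenotypeMatrix}}.
#' @export
genotypeMatrixFromAlignments <- function(alignments, samples,
                                         mafThreshold = 0.05) {
  sites <- unlist(lapply(alignments, callVariableSites), recursive = FALSE)
  if (length(sites) == 0L) {
    return(new("GenotypeMatrix",
               dosage = matrix(numeric(0), nrow = nrow(samples), ncol = 0,
                               dimnames = list(samples$individual_id, NULL)),
               siteInfo = S4Vectors::DataFrame(
                 locus = character(0), column = integer(0),
                 position = integer(0), alleles = character(0),
                 maf = numeric(0), nCalled = integer(0),
                 condensed = logical(0), condensedRule = character(0))))
  }
  buildGenotypeMatrix(sites, samples, mafThreshold = mafThreshold)
}

#' Export the site table
#'
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @return data.frame with locus, 1-based position, alleles, maf, n_called.
#' @export
siteTable <- function(gm) {
  si <- as.data.frame(gm@siteInfo)
  data.frame(locus = si$locus,
             position = ifelse(is.na(si$position), si$column + 1L,
                               si$position),
             alleles = si$alleles,
             maf = si$maf,
             n_called = si$nCalled,
             condensed = si$condensed,
             stringsAsFactors = FALSE)
}
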