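#' Read per-locus FASTA alignments
#'
#' Reads one FASTA file per locus and attaches region labels and genomic
#' offsets from a locus metadata table. Each file must contain an alignment:
#' all records the same length, at least two records, unique names. Locus
#' identifiers default to file basenames without the FASTA extension.
#' Loci absent from the metadata table are assigned region
#' \code{"unlinked"} and an absent offset, with a warning.
#'
#' @param paths character vector of FASTA file paths.
#' @param locusMeta optional data.frame with columns \code{locus_id},
#'   \code{region}, \code{genomic_offset} (see [readLocusMeta()]).
#' @return Named list of \code{\linkS4class{LocusAlignment}} objects.
#' @export
readLocusAlignments <- function(paths, locusMeta = NULL) {
  out <- vector("list", length(paths))
  ids <- character(length(paths))
  for (i in seq_along(paths)) {
    path <- paths[i]
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop("cannot read FASTA '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
    w <- Biostrings::width(seqs)
    if (length(unique(w)) != 1L) {
      stop("ragged alignment in '", path, "': record lengths ",
           paste(unique(w), collapse = ", "), call. = FALSE)
    }
    # headers may carry descriptions after whitespace; keep the first token
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    id <- sub("\\.(fa|fasta|fas|fna)$", "", basename(path),
              ignore.case = TRUE)
    reg <- "unlinked"
    off <- NA_integer_
    if (!is.null(locusMeta) && id %in% locusMeta$locus_id) {
      row <- locusMeta[match(id, locusMeta$locus_id), ]
      reg <- as.character(row$region)
      off <- as.integer(row$genomic_offset)
    } else if (!is.null(locusMeta)) {
      warning("locus '", id, "' not in metadata table; ",
              "using region=unlinked, no offset", call. = FALSE)
    }
    out[[i]] <- LocusAlignment(id, .cleanSequences(as.character(seqs)),
                               region = reg, genomicOffset = off)
    ids[i] <- id
  }
  names(out) <- ids
  out
}

#' Read the sample metadata table
#'
#' Tab-separated table with header columns \code{individual_id},
#' \code{population}, \code{comparison}, \code{phenotype_score} and the two
#' haplotype-name columns \code{hap1}, \code{hap2}. Phenotype scores must be
#' 0, 0.5, 1 or \code{NA}. When the haplotype columns are absent, pairs are
#' inferred as \code{<individual_id>_a} / \code{<individual_id>_b}.
#'
#' @param path path to the TSV file.
#' @return data.frame with one validated row per individual.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("individual_id", "population", "comparison", "phenotype_score")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L) {
    stop("sample table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(c("hap1", "hap2") %in% colnames(df))) {
    df$hap1 <- paste0(df$individual_id, "_a")
    df$hap2 <- paste0(df$individual_id, "_b")
    message("hap1/hap2 columns absent; inferring '_a'/'_b' haplotype names")
  }
  declared <- !is.na(df$phenotype_score) &
    !df$phenotype_score %in% c("NA", "")
  score <- suppressWarnings(as.numeric(df$phenotype_score))
  bad <- declared & (is.na(score) | !(score %in% c(0, 0.5, 1)))
  if (any(bad)) {
    stop("invalid phenotype score for individual(s): ",
         paste(df$individual_id[bad], collapse = ", "),
         " (allowed: 0, 0.5, 1, NA)", call. = FALSE)
  }
  df$phenotype_score <- score
  if (anyDuplicated(df$individual_id)) {
    stop("duplicated individual_id in sample table", call. = FALSE)
  }
  haps <- c(df$hap1, df$hap2)
  if (anyDuplicated(haps)) {
    stop("haplotype assigned twice: ",
         paste(unique(haps[duplicated(haps)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read the locus metadata table
#'
#' Tab-separated table with columns \code{locus_id}, \code{region},
#' \code{genomic_offset} and optionally \code{notes}. Offsets may be
#' \code{NA} for loci not placed on the shared coordinate axis.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per locus.
#' @export
readLocusMeta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "region", "genomic_offset")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L) {
    stop("locus metadata is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$locus_id)) {
    stop("duplicated locus_id in metadata table", call. = FALSE)
  }
  badReg <- !df$region %in% .regionLevels
  if (any(badReg)) {
    stop("invalid region label(s): ",
         paste(unique(df$region[badReg]), collapse = ", "), call. = FALSE)
  }
  df$genomic_offset <- suppressWarnings(as.integer(df$genomic_offset))
  if (!"notes" %in% colnames(df)) df$notes <- ""
  df
}

#' Write a results table as TSV
#'
#' Writes any of the pipeline's result data.frames with a stable column
#' order (the order of the input), doubles at 6 significant digits and site
#' positions already 1-based. An empty data.frame yields a header-only file.
#'
#' @param records a data.frame of results.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
writeResultsTable <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  records <- .signifCols(records, 6L)
  ok <- tryCatch({
    suppressWarnings(utils::write.table(records, path, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write results table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Match samples to the haplotypes present in an alignment
#'
#' Individuals whose two haplotype sequences are not both present in the
#' alignment are excluded from that locus, with a warning reporting the
#' count (sequencing failures at single loci are handled per locus).
#'
#' @param aln a \code{\linkS4class{LocusAlignment}}.
#' @param samples sample data.frame from [readSampleTable()].
#' @return The subset of \code{samples} usable at this locus; the number of
#'   excluded individuals is attached as attribute \code{"nExcluded"}.
#' @export
matchSamplesToAlignment <- function(aln, samples) {
  nm <- sequenceNames(aln)
  ok <- samples$hap1 %in% nm & samples$hap2 %in% nm
  if (any(!ok)) {
    warning(sum(!ok), " individual(s) excluded at locus '",
            locusId(aln), "' (haplotype sequence absent)", call. = FALSE)
  }
  out <- samples[ok, , drop = FALSE]
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA per locus plus \code{samples.tsv} and \code{loci.tsv},
#' in the formats read back by [readLocusAlignments()],
#' [readSampleTable()] and [readLocusMeta()]. Output is byte-identical for
#' identical simulated input.
#'
#' @param sim result of [simulateTwoPopDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (aln in sim$alignments) {
    p <- file.path(dir, paste0(locusId(aln), ".fasta"))
    Biostrings::writeXStringSet(aln@sequences, p)
    paths <- c(paths, p)
  }
  ps <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, ps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pl <- file.path(dir, "loci.tsv")
  utils::write.table(sim$locusMeta, pl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, ps, pl))
}
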