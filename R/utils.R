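# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.regionLevels <- c("HmYb", "HmB", "unlinked")

# harmonic sums used by Watterson's theta and Tajima's D
.harmonic <- function(n, power = 1) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1)^power)
}

# alignment as a character matrix, rows = haplotypes; optionally subset
.alnMatrix <- function(aln, haplotypes = NULL) {
  m <- as.matrix(aln@sequences)
  if (!is.null(haplotypes)) {
    missing <- setdiff(haplotypes, rownames(m))
    if (length(missing) > 0L) {
      stop("haplotypes not present in alignment '", aln@locusId, "': ",
           paste(missing, collapse = ", "))
    }
    m <- m[haplotypes, , drop = FALSE]
  }
  m
}

# indel trimming: columns containing any gap are excluded entirely
.retainedColumns <- function(m) {
  which(colSums(m == "-") == 0L)
}

# signif() that leaves non-numeric and integer columns alone
.signifCols <- function(df, digits = 6L) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  df
}
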