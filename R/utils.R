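#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nonempty <- nchar(x) > 0L
  if (any(nonempty)) {
    out[nonempty] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nonempty])
    ))
  }
  out
}

#' GC fraction of nucleotide strings
#'
#' Fraction of G+C among A/C/G/T bases; N bases are excluded from the
#' denominator.
#'
#' @param x character vector of nucleotide strings (pooled before counting).
#' @return single fraction in `[0, 1]`, or `NA` if no unambiguous base.
#' @export
gc_fraction <- function(x) {
  x <- x[nchar(x) > 0L]
  if (length(x) == 0) return(NA_real_)
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(x), letters = c("A", "C", "G", "T")
  ))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts[["C"]] + counts[["G"]]) / tot)
}

# random nucleotide string(s) with a target GC content
random_seq <- function(n_bases, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# depth lookup on a CoverageTrack: genomic 0-based positions; positions
# outside the chromosome return NA
depth_at <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    d <- track$depth[[ch]]
    idx <- which(chrom == ch)
    p <- pos[idx]
    ok <- !is.na(p) & p >= 0 & p < length(d)
    out[idx[ok]] <- d[p[ok] + 1L]
  }
  out
}
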