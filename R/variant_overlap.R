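#' Parse variant positions from a VCF file
#'
#' Extracts one 0-based position per record (indels contribute their POS
#' anchor). Records failing the FILTER column (anything other than `PASS`
#' or `.`) are excluded by default.
#'
#' @param path path to a VCF v4.x file (plain text or bgzipped).
#' @param keep_filtered keep non-PASS records (default `FALSE`).
#' @return data.frame `chrom`, `pos` (0-based), unique positions, with
#'   attribute `n_records` (records read).
#' @export
parse_vcf <- function(path, keep_filtered = FALSE) {
  stopifnot(file.exists(path))
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) NULL
  )
  empty <- data.frame(chrom = character(0), pos = numeric(0))
  if (is.null(v) || nrow(v@fix) == 0) {
    attr(empty, "n_records") <- 0L
    return(empty)
  }
  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  filt <- fix[, "FILTER"]
  bad <- is.na(pos) | is.na(chrom)
  if (any(bad)) {
    warning(sum(bad), " malformed VCF record(s) skipped")
  }
  keep <- !bad
  if (!keep_filtered) {
    keep <- keep & (is.na(filt) | filt %in% c("PASS", "."))
  }
  out <- unique(data.frame(chrom = chrom[keep], pos = pos[keep] - 1))
  rownames(out) <- NULL
  attr(out, "n_records") <- nrow(fix)
  out
}

#' Variant rates at splice-site dinucleotides versus background
#'
#' Compares the per-base variant rate over the four border bases of every
#' intron (the donor and acceptor dinucleotides) with the rate over a
#' background set of intervals (conventionally the internal exonic bases of
#' representative transcripts). Overlapping positions are deduplicated
#' before counting.
#'
#' @param variants data.frame from [parse_vcf()].
#' @param introns data.frame from [extract_introns()].
#' @param background data.frame of 0-based half-open intervals (`chrom`,
#'   `start`, `end`).
#' @return list with `rate_splice`, `rate_background`, `ratio`,
#'   `n_splice_bases`, `n_background_bases`, `n_splice_variants`,
#'   `n_background_variants`. `ratio` is `NA` with a warning when the
#'   background rate is 0.
#' @export
splice_variant_rates <- function(variants, introns, background) {
  if (nrow(background) == 0 || sum(background$end - background$start) == 0) {
    stop("background has zero length")
  }
  border <- unique(data.frame(
    chrom = rep(introns$chrom, 4),
    pos = c(introns$start, introns$start + 1, introns$end - 2,
            introns$end - 1)
  ))
  if (nrow(border) == 0) stop("no introns supplied")
  vkey <- paste0(variants$chrom, ":", variants$pos)
  n_splice_var <- sum(paste0(border$chrom, ":", border$pos) %in% vkey)
  rate_splice <- n_splice_var / nrow(border)

  bg_pos <- data.frame(
    chrom = rep(background$chrom, background$end - background$start),
    pos = sequence(background$end - background$start,
                   from = background$start)
  )
  bg_pos <- unique(bg_pos)
  n_bg_var <- sum(paste0(bg_pos$chrom, ":", bg_pos$pos) %in% vkey)
  rate_bg <- n_bg_var / nrow(bg_pos)

  ratio <- if (rate_bg > 0) rate_splice / rate_bg else {
    warning("background variant rate is 0; ratio undefined")
    NA_real_
  }
  list(rate_splice = rate_splice, rate_background = rate_bg, ratio = ratio,
       n_splice_bases = nrow(border), n_background_bases = nrow(bg_pos),
       n_splice_variants = n_splice_var, n_background_variants = n_bg_var)
}

#' Internal exonic background intervals for variant-rate comparison
#'
#' All exonic bases of the supplied transcripts, as 0-based half-open
#' intervals.
#'
#' @param transcripts list of `transcript_model` objects.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
exonic_background <- function(transcripts) {
  rows <- lapply(transcripts, function(t) {
    data.frame(chrom = t$chrom, start = t$exons[, 1], end = t$exons[, 2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
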