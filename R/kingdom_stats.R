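#' Shannon diversity of a splice-site combination spectrum
#'
#' `H = -sum(p * ln p)` in nats over the combination frequencies. An
#' optional exclusion set (e.g. GT-AG and GC-AG, to focus on the rarer
#' combinations) is removed first and the remaining mass renormalised.
#'
#' @param freqs named numeric vector of combination frequencies summing
#'   to 1.
#' @param exclude character vector of combination names to drop before
#'   renormalisation.
#' @return diversity in nats; 0 for a single combination; `NA` with a
#'   warning when nothing remains after exclusion.
#' @export
shannon_diversity <- function(freqs, exclude = character(0)) {
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop("frequencies must sum to 1 before exclusion")
  }
  p <- freqs[!(names(freqs) %in% exclude)]
  p <- p[p > 0]
  if (length(p) == 0) {
    warning("no combinations left after exclusion; diversity undefined")
    return(NA_real_)
  }
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Pearson correlation between two per-species GC measures
#'
#' Standard Pearson correlation with a two-sided p-value, as used to relate
#' genomic GC content to the occurrence-weighted GC content of splice-site
#' combinations across species.
#'
#' @param x,y numeric vectors (one value per species, length >= 3).
#' @return list with `r`, `p` and `n`. Zero variance in either axis gives
#'   `r = NA` with a warning.
#' @export
gc_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 species")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare combination frequencies between species groups
#'
#' Two groups are compared with a two-sided Mann-Whitney U test (normal
#' approximation with tie and continuity correction); three or more with a
#' Kruskal-Wallis H test.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @return list with `method`, `statistic` (U or H) and `p.value`.
#' @export
compare_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !is.numeric(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  if (length(groups) == 2) {
    ht <- stats::wilcox.test(groups[[1]], groups[[2]],
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    # wilcox.test's W statistic is the Mann-Whitney U of the first sample
    list(method = "mann-whitney-u", statistic = unname(ht$statistic),
         p.value = ht$p.value)
  } else {
    ht <- stats::kruskal.test(groups)
    list(method = "kruskal-wallis", statistic = unname(ht$statistic),
         p.value = ht$p.value)
  }
}

#' CDS offsets of a transcript's introns
#'
#' For each intron (transcript orientation), the number of coding bases
#' upstream of the intron. Introns not flanked by CDS on both sides (UTR
#' introns, or transcripts without CDS) get `NA`.
#'
#' @param t a `transcript_model`.
#' @return numeric vector, one value per intron in transcript orientation
#'   order (empty when the transcript has < 2 exons).
#' @export
cds_offsets <- function(t) {
  iv <- intron_intervals(t)
  if (nrow(iv) == 0) return(numeric(0))
  out <- rep(NA_real_, nrow(iv))
  if (nrow(t$cds) > 0) {
    cds_min <- min(t$cds[, 1])
    cds_max <- max(t$cds[, 2])
    inside <- iv$start >= cds_min & iv$end <= cds_max
    for (k in which(inside)) {
      if (t$strand == "+") {
        out[k] <- sum(pmax(0, pmin(t$cds[, 2], iv$start[k]) - t$cds[, 1]))
      } else {
        out[k] <- sum(pmax(0, t$cds[, 2] - pmax(t$cds[, 1], iv$end[k])))
      }
    }
  }
  # return in transcript orientation order (intron_index 1, 2, ...)
  out[order(iv$intron_index)]
}

#' Frame and stop-codon check for intron retention
#'
#' A retained intron leaves the reading frame intact only when its length
#' is divisible by three, and leaves the protein unchanged beyond an
#' insertion only when it contains no stop codon in the reading frame
#' continuing from the upstream CDS. The frame starts
#' `(3 - cds_offset %% 3) %% 3` bases into the intron; codons are scanned
#' fully within the intron.
#'
#' @param sequence intron sequence(s) in transcript orientation.
#' @param cds_offset number(s) of coding bases upstream of the intron
#'   (recycled); `NA` (UTR intron) yields `NA`.
#' @return logical vector: `TRUE` when length is divisible by 3 and no
#'   in-frame TAA/TAG/TGA occurs.
#' @export
intron_frame_check <- function(sequence, cds_offset = 0) {
  n <- max(length(sequence), length(cds_offset))
  sequence <- rep_len(sequence, n)
  cds_offset <- rep_len(cds_offset, n)
  vapply(seq_len(n), function(i) {
    if (is.na(cds_offset[i])) return(NA)
    s <- sequence[i]
    len <- nchar(s)
    if (len %% 3 != 0) return(FALSE)
    off <- (3 - cds_offset[i] %% 3) %% 3
    starts <- seq.int(off + 1, by = 3, length.out = (len - off) %/% 3)
    if (length(starts) == 0) return(TRUE)
    codons <- substring(s, starts, starts + 2)
    !any(codons %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
}

# qualifies flags for a whole intron set; needs the transcript models to
# anchor the frame
frame_qualifies <- function(introns, transcripts) {
  # index models by their transcript id, whatever the list names are
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")
  offs <- rep(NA_real_, nrow(introns))
  for (tid in unique(introns$transcript_id)) {
    t <- transcripts[[tid]]
    if (is.null(t)) next
    o <- cds_offsets(t)
    idx <- which(introns$transcript_id == tid)
    offs[idx] <- o[introns$intron_index[idx]]
  }
  intron_frame_check(introns$sequence, offs)
}

#' Per-class proportions of retention-tolerant introns
#'
#' Summarises, per splice-site combination class (or per combination), the
#' proportion of evaluated introns whose length is divisible by three and
#' that are free of in-frame stop codons.
#'
#' @param introns data.frame from [extract_introns()].
#' @param transcripts named list of `transcript_model` objects (for CDS
#'   phase); names must cover the introns' transcript ids.
#' @param by `"class"` (canonical / major / minor) or `"combination"`.
#' @return data.frame `group`, `n_qualifying`, `n_total`, `proportion`.
#'   UTR introns (no CDS anchor) are excluded from `n_total`; empty groups
#'   are omitted.
#' @export
frame_summary <- function(introns, transcripts, by = c("class",
                                                       "combination")) {
  by <- match.arg(by)
  keep <- introns[!introns$ambiguous, , drop = FALSE]
  q <- frame_qualifies(keep, transcripts)
  grp <- if (by == "class") {
    classify_combination(keep$donor, keep$acceptor)
  } else {
    paste(keep$donor, keep$acceptor, sep = "-")
  }
  evald <- !is.na(q)
  grp <- grp[evald]
  q <- q[evald]
  if (length(grp) == 0) {
    return(data.frame(group = character(0), n_qualifying = integer(0),
                      n_total = integer(0), proportion = numeric(0)))
  }
  agg <- stats::aggregate(q, list(group = grp),
                          function(v) c(sum(v), length(v)))
  out <- data.frame(group = agg$group,
                    n_qualifying = agg$x[, 1],
                    n_total = agg$x[, 2])
  out$proportion <- out$n_qualifying / out$n_total
  out
}

#' One-row per-species summary of splice-site statistics
#'
#' Collects the quantities reported per species in cross-kingdom
#' comparisons: frequencies of GT-AG, GC-AG, AT-AC and all remaining
#' combinations, genomic / intronic / splice-site GC content, introns per
#' gene, and Shannon diversity over the full spectrum (`H_all`) and over
#' the spectrum excluding GT-AG and GC-AG (`H_excl`, renormalised).
#'
#' @param genome genome from [parse_genome()].
#' @param introns data.frame from [extract_introns()] (representative
#'   transcripts).
#' @param table a [combination_table()] of the same introns.
#' @param n_genes number of genes considered (genes without introns count
#'   in the denominator of introns per gene).
#' @param species_id,kingdom labels carried into the row.
#' @return one-row data.frame.
#' @export
species_summary <- function(genome, introns, table, n_genes,
                            species_id = NA_character_,
                            kingdom = NA_character_) {
  freqs <- stats::setNames(table$frequency, table$combination)
  freq_of <- function(c) if (c %in% names(freqs)) freqs[[c]] else 0
  data.frame(
    species_id = species_id,
    kingdom = kingdom,
    gt_ag = freq_of("GT-AG"),
    gc_ag = freq_of("GC-AG"),
    at_ac = freq_of("AT-AC"),
    others = 1 - freq_of("GT-AG") - freq_of("GC-AG") - freq_of("AT-AC"),
    genome_gc = gc_fraction(genome),
    intron_gc = gc_fraction(introns$sequence[!introns$ambiguous]),
    splice_gc = weighted_splice_gc(table),
    introns_per_gene = nrow(introns) / n_genes,
    H_all = shannon_diversity(freqs),
    H_excl = shannon_diversity(freqs, exclude = c("GT-AG", "GC-AG"))
  )
}
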