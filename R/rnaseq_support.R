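#' Load RNA-Seq coverage evidence
#'
#' Builds a per-base depth track plus a table of junction-spanning read
#' counts. Input is either a coordinate-sorted indexed BAM file or a
#' 4-column interval-depth TSV (`chrom start end depth`, 0-based half-open)
#' together with a junction TSV (`chrom start end reads`, intron intervals
#' 0-based half-open). TSV input is taken as already filtered; for BAM
#' input, reads are filtered to primary alignments, excluding multi-mapped
#' reads (NH tag > 1), requiring >= 95% alignment similarity (NM tag) and
#' >= 90% of the read length aligned where those tags/fields permit the
#' check. Junctions are tallied from split (N-op) alignments.
#'
#' @param coverage path to a BAM file (`.bam`) or an interval-depth TSV.
#' @param genome genome from [parse_genome()]; references must match.
#' @param junctions path to a junction TSV (required for TSV input; ignored
#'   for BAM input). `NULL` yields an empty junction table.
#' @param min_similarity,min_read_fraction BAM filter thresholds.
#' @return object of class `coverage_track`: list with `depth` (named list
#'   of integer vectors, one per chromosome, length = chromosome length)
#'   and `junctions` (data.frame `chrom`, `start`, `end`, `reads`).
#' @export
load_coverage <- function(coverage, genome, junctions = NULL,
                          min_similarity = 0.95, min_read_fraction = 0.90) {
  if (grepl("\\.bam$", coverage, ignore.case = TRUE)) {
    return(load_coverage_bam(coverage, genome, min_similarity,
                             min_read_fraction))
  }
  cov <- utils::read.table(coverage, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "depth"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  bad <- setdiff(unique(cov$chrom), names(genome))
  if (length(bad)) {
    stop("coverage references absent from genome: ",
         paste(bad, collapse = ", "))
  }
  depth <- lapply(nchar(genome), function(L) integer(L))
  for (ch in unique(cov$chrom)) {
    rows <- cov[cov$chrom == ch, , drop = FALSE]
    d <- depth[[ch]]
    idx <- sequence(rows$end - rows$start, from = rows$start + 1)
    d[idx] <- rep(as.integer(rows$depth), rows$end - rows$start)
    depth[[ch]] <- d
  }
  jx <- empty_junctions()
  if (!is.null(junctions)) {
    jx <- utils::read.table(junctions, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "reads"),
                            colClasses = c("character", "numeric",
                                           "numeric", "numeric"))
    bad <- setdiff(unique(jx$chrom), names(genome))
    if (length(bad)) {
      stop("junction references absent from genome: ",
           paste(bad, collapse = ", "))
    }
  }
  new_coverage_track(depth, jx)
}

empty_junctions <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             reads = numeric(0))
}

new_coverage_track <- function(depth, junctions) {
  structure(list(depth = depth, junctions = junctions),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %d junction(s)\n",
              length(x$depth), nrow(x$junctions)))
  invisible(x)
}

# BAM branch of load_coverage; requires GenomicAlignments/Rsamtools
load_coverage_bam <- function(path, genome, min_similarity,
                              min_read_fraction) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the GenomicAlignments and Rsamtools packages")
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, tag = c("NM", "NH"),
                                   what = "qwidth")
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  bad <- setdiff(as.character(GenomeInfoDb_seqlevelsInUse(gal)),
                 names(genome))
  if (length(bad)) {
    stop("BAM references absent from genome: ", paste(bad, collapse = ", "))
  }
  meta <- S4Vectors::mcols(gal)
  keep <- rep(TRUE, length(gal))
  if (!is.null(meta$NH)) keep <- keep & (is.na(meta$NH) | meta$NH == 1)
  qw <- meta$qwidth
  aln_q <- GenomicAlignments::cigarWidthAlongQuerySpace(
    GenomicAlignments::cigar(gal), after.soft.clipping = TRUE)
  ok_frac <- is.na(qw) | (aln_q / qw >= min_read_fraction)
  keep <- keep & ok_frac
  if (!is.null(meta$NM)) {
    sim <- 1 - meta$NM / aln_q
    keep <- keep & (is.na(sim) | sim >= min_similarity)
  }
  gal <- gal[keep]
  cov <- GenomicAlignments::coverage(gal)
  depth <- lapply(nchar(genome), function(L) integer(L))
  for (ch in names(cov)) {
    v <- as.integer(cov[[ch]])
    L <- length(depth[[ch]])
    depth[[ch]][seq_len(min(L, length(v)))] <- v[seq_len(min(L, length(v)))]
  }
  jx <- GenomicAlignments::junctions(gal)
  jxu <- unlist(jx, use.names = FALSE)
  if (length(jxu)) {
    key <- paste0(as.character(GenomicRanges::seqnames(jxu)), ":",
                  BiocGenerics::start(jxu) - 1L, "-",
                  BiocGenerics::end(jxu))
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "[:-]"))
    jdf <- data.frame(chrom = parts[, 1],
                      start = as.numeric(parts[, 2]),
                      end = as.numeric(parts[, 3]),
                      reads = as.numeric(tab))
  } else {
    jdf <- empty_junctions()
  }
  new_coverage_track(depth, jdf)
}

# small shim: seqlevelsInUse lives in GenomeInfoDb, pulled in by the
# GenomicAlignments dependency chain
GenomeInfoDb_seqlevelsInUse <- function(x) {
  getExportedValue("GenomeInfoDb", "seqlevelsInUse")(x)
}

# border depth positions of introns (genomic 0-based), strand-aware:
# exon5/intron5 flank the 5' (donor) border, intron3/exon3 the 3' border
border_positions <- function(introns) {
  plus <- introns$strand == "+"
  data.frame(
    exon5 = ifelse(plus, introns$start - 1, introns$end),
    intron5 = ifelse(plus, introns$start, introns$end - 1),
    intron3 = ifelse(plus, introns$end - 1, introns$start),
    exon3 = ifelse(plus, introns$end, introns$start - 1)
  )
}

junction_reads <- function(track, chrom, start, end) {
  jx <- track$junctions
  key <- paste0(chrom, ":", start, "-", end)
  jkey <- paste0(jx$chrom, ":", jx$start, "-", jx$end)
  out <- jx$reads[match(key, jkey)]
  out[is.na(out)] <- 0
  out
}

#' Validate annotated splice sites against RNA-Seq evidence
#'
#' An intron's splice sites are supported when the junction is spanned by at
#' least `min_reads` split-aligned reads and the read depth drops by at
#' least `drop` (default 20%) when moving from the exon into the intron at
#' both borders. The threshold comparisons are inclusive: a drop of exactly
#' 20% passes. A border with zero exonic coverage makes the intron
#' unsupported and is flagged `no_coverage`.
#'
#' @param introns data.frame from [extract_introns()].
#' @param track a `coverage_track` from [load_coverage()].
#' @param min_reads minimum junction-spanning reads (default 3).
#' @param drop minimum relative coverage drop at each border (default 0.2).
#' @return data.frame with intron keys plus `spanning_reads`, `exon_cov_5`,
#'   `intron_cov_5`, `exon_cov_3`, `intron_cov_3`, `supported`, `flag`.
#' @export
validate_splice_sites <- function(introns, track, min_reads = 3,
                                  drop = 0.2) {
  stopifnot(min_reads >= 0, drop >= 0, drop <= 1)
  bp <- border_positions(introns)
  out <- introns[, c("transcript_id", "gene_id", "intron_index", "chrom",
                     "start", "end", "strand")]
  out$spanning_reads <- junction_reads(track, introns$chrom, introns$start,
                                       introns$end)
  out$exon_cov_5 <- depth_at(track, introns$chrom, bp$exon5)
  out$intron_cov_5 <- depth_at(track, introns$chrom, bp$intron5)
  out$intron_cov_3 <- depth_at(track, introns$chrom, bp$intron3)
  out$exon_cov_3 <- depth_at(track, introns$chrom, bp$exon3)
  # positions off the chromosome end count as zero coverage
  for (col in c("exon_cov_5", "intron_cov_5", "intron_cov_3", "exon_cov_3")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  no_cov <- out$exon_cov_5 == 0 | out$exon_cov_3 == 0
  drop5 <- out$intron_cov_5 <= (1 - drop) * out$exon_cov_5
  drop3 <- out$intron_cov_3 <= (1 - drop) * out$exon_cov_3
  out$supported <- !no_cov & out$spanning_reads >= min_reads & drop5 & drop3
  out$flag <- ifelse(no_cov, "no_coverage", "")
  rownames(out) <- NULL
  out
}

#' Per-intron splice-site usage from coverage
#'
#' Usage of each border is the relative coverage drop from the flanking
#' exonic base into the intron, clamped to `[0, 1]`:
#' `max(0, 1 - intron_cov / exon_cov)`. A fully spliced intron has usage 1
#' at both ends; a fully retained intron has usage 0. `delta` is
#' `usage_5 - usage_3`; its distribution summarises the relative
#' flexibility of the two splice sites. Borders with zero exonic coverage
#' get usage 0 and flag `no_coverage`.
#'
#' @param introns data.frame from [extract_introns()].
#' @param track a `coverage_track`.
#' @return data.frame with intron keys plus `usage_5`, `usage_3`, `delta`,
#'   `flag`.
#' @export
splice_usage <- function(introns, track) {
  bp <- border_positions(introns)
  e5 <- depth_at(track, introns$chrom, bp$exon5)
  i5 <- depth_at(track, introns$chrom, bp$intron5)
  i3 <- depth_at(track, introns$chrom, bp$intron3)
  e3 <- depth_at(track, introns$chrom, bp$exon3)
  e5[is.na(e5)] <- 0; i5[is.na(i5)] <- 0
  i3[is.na(i3)] <- 0; e3[is.na(e3)] <- 0
  usage5 <- ifelse(e5 > 0, pmax(0, 1 - i5 / e5), 0)
  usage3 <- ifelse(e3 > 0, pmax(0, 1 - i3 / e3), 0)
  out <- introns[, c("transcript_id", "gene_id", "intron_index", "chrom",
                     "start", "end", "strand")]
  out$usage_5 <- usage5
  out$usage_3 <- usage3
  out$delta <- usage5 - usage3
  out$flag <- ifelse(e5 == 0 | e3 == 0, "no_coverage", "")
  rownames(out) <- NULL
  out
}

#' Fragments per kilobase of transcript per million assigned fragments
#'
#' @param read_count fragments assigned to the gene.
#' @param transcript_length transcript length in bases (> 0).
#' @param total_assigned total assigned fragments in the library (> 0).
#' @return FPKM value(s): `read_count / ((transcript_length/1e3) *
#'   (total_assigned/1e6))`.
#' @export
fpkm <- function(read_count, transcript_length, total_assigned) {
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  if (any(total_assigned <= 0)) stop("total_assigned must be > 0")
  read_count / ((transcript_length / 1e3) * (total_assigned / 1e6))
}

#' Gene expression classes from splice-site combinations
#'
#' Classifies genes by the presence/absence of non-canonical combinations
#' into four (non-exclusive, except the first) groups: only-GT-AG, has
#' GC-AG, has AT-AC, has a minor non-canonical combination.
#'
#' @param introns data.frame from [extract_introns()] (must carry
#'   `gene_id`).
#' @return data.frame `gene_id`, `gt_ag_only`, `has_gc_ag`, `has_at_ac`,
#'   `has_minor` (logical).
#' @export
gene_classes <- function(introns) {
  keep <- introns[!introns$ambiguous, , drop = FALSE]
  combo <- paste(keep$donor, keep$acceptor, sep = "-")
  cls <- classify_combination(keep$donor, keep$acceptor)
  split_cls <- split(cls, keep$gene_id)
  genes <- names(split_cls)
  has_gc <- vapply(split(combo, keep$gene_id),
                   function(v) any(v == "GC-AG"), logical(1))
  has_at <- vapply(split(combo, keep$gene_id),
                   function(v) any(v == "AT-AC"), logical(1))
  has_minor <- vapply(split_cls, function(v) any(v == "minor_noncanonical"),
                      logical(1))
  data.frame(gene_id = genes,
             gt_ag_only = !(has_gc | has_at | has_minor),
             has_gc_ag = unname(has_gc),
             has_at_ac = unname(has_at),
             has_minor = unname(has_minor))
}

#' Cumulative relative FPKM bin sizes per gene class
#'
#' Mirrors an expression-bin comparison of gene groups: outlier genes above
#' the `outlier_quantile` of FPKM are dropped, the remaining genes are
#' binned on FPKM per class, and relative bin sizes plus their cumulative
#' sums are returned. A class whose cumulative curve rises late is depleted
#' of lowly expressed genes.
#'
#' @param records data.frame with columns `gene_id`, `fpkm` and logical
#'   class columns (e.g. from [gene_classes()], merged with FPKM values).
#' @param class_cols names of the logical class columns to compare.
#' @param bin_edges numeric vector of bin edges; default 20 equal-width
#'   bins over the retained FPKM range.
#' @param outlier_quantile FPKM quantile above which genes are excluded
#'   (default 0.99).
#' @return data.frame `class`, `bin` (1-based index), `upper` (bin upper
#'   edge), `relative`, `cumulative`. Empty classes are omitted with a
#'   warning.
#' @export
expression_bins <- function(records,
                            class_cols = c("gt_ag_only", "has_gc_ag",
                                           "has_at_ac", "has_minor"),
                            bin_edges = NULL, outlier_quantile = 0.99) {
  stopifnot(all(c("fpkm", class_cols) %in% names(records)))
  thr <- stats::quantile(records$fpkm, outlier_quantile, names = FALSE)
  kept <- records[records$fpkm <= thr, , drop = FALSE]
  if (is.null(bin_edges)) {
    hi <- max(kept$fpkm, 1e-9)
    bin_edges <- seq(0, hi, length.out = 21)
  }
  out <- list()
  for (cl in class_cols) {
    vals <- kept$fpkm[kept[[cl]]]
    if (length(vals) == 0) {
      warning("class ", cl, " has no genes after outlier exclusion; omitted")
      next
    }
    cuts <- cut(vals, breaks = bin_edges, include.lowest = TRUE,
                right = TRUE)
    counts <- as.integer(table(cuts))
    rel <- counts / sum(counts)
    out[[cl]] <- data.frame(class = cl, bin = seq_along(counts),
                            upper = bin_edges[-1], relative = rel,
                            cumulative = cumsum(rel))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Isoform-presence estimate per intron
#'
#' Compares the local expression around a splice site (mean depth of the
#' two exonic bases directly flanking the intron) with a global estimate of
#' the transcript's sequencing coverage, `200 * read_count /
#' transcript_length` (200 bp per fragment, assuming 2 x 100 nt reads).
#' Values near zero indicate the intron sits in the dominant isoform; a
#' strongly negative difference indicates the intron belongs to a minor
#' isoform.
#'
#' @param introns data.frame from [extract_introns()].
#' @param track a `coverage_track`.
#' @param expression data.frame with `gene_id`, `read_count`,
#'   `transcript_length`.
#' @return data.frame with intron keys plus `local`, `global`,
#'   `difference` (`local - global`).
#' @export
isoform_presence <- function(introns, track, expression) {
  m <- match(introns$gene_id, expression$gene_id)
  if (anyNA(m)) {
    stop("expression records missing for gene(s): ",
         paste(unique(introns$gene_id[is.na(m)]), collapse = ", "))
  }
  left <- depth_at(track, introns$chrom, introns$start - 1)
  right <- depth_at(track, introns$chrom, introns$end)
  left[is.na(left)] <- 0
  right[is.na(right)] <- 0
  local <- (left + right) / 2
  global <- 200 * expression$read_count[m] / expression$transcript_length[m]
  out <- introns[, c("transcript_id", "gene_id", "intron_index", "chrom",
                     "start", "end", "strand")]
  out$local <- local
  out$global <- global
  out$difference <- local - global
  rownames(out) <- NULL
  out
}
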