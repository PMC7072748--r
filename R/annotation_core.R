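#' Read a genome FASTA file
#'
#' Loads all sequences, uppercases them and maps any character outside
#' A/C/G/T/N (IUPAC ambiguity codes and anything else) to N.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per chromosome/scaffold.
#'   Names are the first whitespace-delimited token of each header.
#' @export
parse_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  out <- gsub("[^ACGTN]", "N", out)
  names(out) <- ids
  out
}

#' Transcript model
#'
#' A light container for one transcript: ordered exon (and optionally CDS)
#' intervals on one strand of one chromosome. All intervals use 0-based
#' half-open genomic coordinates and are sorted by genomic start regardless
#' of strand.
#'
#' @param transcript_id,gene_id,chrom,strand identifiers; strand is
#'   `"+"` or `"-"`.
#' @param exons,cds two-column matrices (`start`, `end`), 0-based half-open;
#'   `cds` may have zero rows.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) == 0) stop("transcript must have at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (is.null(cds) || length(cds) == 0) {
    cds <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  } else {
    cds <- matrix(as.numeric(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s strand %s, %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              paste0(x$exons[1, 1], "-", x$exons[nrow(x$exons), 2]),
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Parse a GFF3 annotation into transcript models
#'
#' Reads gene/mRNA/exon/CDS features and builds one [transcript_model()] per
#' mRNA (or `transcript`) feature. GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention at this boundary.
#' Exons whose coordinates fall outside the chromosome reject the whole
#' transcript with a warning; exons whose Parent cannot be resolved are
#' dropped with a warning.
#'
#' @param path path to a GFF3 file.
#' @param genome genome from [parse_genome()]; used for bounds checking.
#' @return named list of `transcript_model` objects (names = transcript ids).
#' @export
parse_annotation <- function(path, genome) {
  stopifnot(file.exists(path))
  gff <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gff)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) {
    vapply(p, function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }

  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(tx) == 0) {
    warning("no mRNA/transcript features in ", path)
    return(structure(list(), names = character(0)))
  }
  tx_gene <- first_parent(tx$Parent)
  tx_gene[is.na(tx_gene)] <- tx$ID[is.na(tx_gene)]
  tx_ids <- tx$ID

  sub_feats <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  sub_parent <- first_parent(sub_feats$Parent)
  orphan <- !(sub_parent %in% tx_ids)
  if (any(orphan)) {
    warning(sum(orphan), " exon/CDS feature(s) with unresolvable Parent ",
            "dropped")
    sub_feats <- sub_feats[!orphan, , drop = FALSE]
    sub_parent <- sub_parent[!orphan]
  }

  models <- vector("list", nrow(tx))
  keep <- logical(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx_ids[i]
    feats <- sub_feats[sub_parent == id, , drop = FALSE]
    ex <- feats[feats$type == "exon", , drop = FALSE]
    cd <- feats[feats$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0 && nrow(cd) > 0) ex <- cd  # CDS-only annotations
    if (nrow(ex) == 0) {
      warning("transcript ", id, " has no exon features; dropped")
      next
    }
    chrom <- tx$seqnames[i]
    if (!chrom %in% names(genome)) {
      warning("transcript ", id, " on unknown chromosome ", chrom,
              "; dropped")
      next
    }
    chrom_len <- nchar(genome[[chrom]])
    # GFF3 1-based inclusive -> 0-based half-open
    ex_m <- cbind(start = ex$start - 1, end = ex$end)
    cd_m <- if (nrow(cd)) cbind(start = cd$start - 1, end = cd$end) else NULL
    if (any(ex_m[, 1] < 0 | ex_m[, 2] > chrom_len)) {
      warning("transcript ", id, " has exon(s) outside chromosome bounds; ",
              "rejected")
      next
    }
    models[[i]] <- transcript_model(id, tx_gene[i], chrom, tx$strand[i],
                                    ex_m, cd_m)
    keep[i] <- TRUE
  }
  models <- models[keep]
  names(models) <- tx_ids[keep]
  models
}

#' Select the representative transcript of a gene
#'
#' Picks one transcript per gene for counting so isoforms are not counted
#' twice: longest total CDS length, ties broken by longest total exonic
#' length, then by lexicographically smallest transcript id.
#'
#' @param transcripts non-empty list of `transcript_model` objects of one
#'   gene.
#' @return a single `transcript_model`.
#' @export
select_representative <- function(transcripts) {
  if (length(transcripts) == 0) stop("empty transcript list")
  gene_ids <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  if (length(gene_ids) > 1) {
    stop("transcripts belong to multiple genes: ",
         paste(gene_ids, collapse = ", "))
  }
  cds_len <- vapply(transcripts, function(t) sum(t$cds[, 2] - t$cds[, 1]),
                    numeric(1))
  ex_len <- vapply(transcripts, function(t) sum(t$exons[, 2] - t$exons[, 1]),
                   numeric(1))
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  ord <- order(-cds_len, -ex_len, ids)
  transcripts[[ord[1]]]
}

#' Group transcripts by gene and select representatives
#'
#' @param transcripts list of `transcript_model` objects (several genes).
#' @return named list of one representative `transcript_model` per gene.
#' @export
representative_transcripts <- function(transcripts) {
  genes <- vapply(transcripts, `[[`, character(1), "gene_id")
  out <- lapply(split(transcripts, genes), select_representative)
  out[order(names(out))]
}

# internal: intron genomic intervals of one transcript (0-based half-open),
# with transcript-orientation index
intron_intervals <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      intron_index = integer(0)))
  }
  start <- t$exons[-n, 2]
  end <- t$exons[-1, 1]
  idx <- if (t$strand == "+") seq_len(n - 1) else rev(seq_len(n - 1))
  data.frame(start = start, end = end, intron_index = idx)
}

#' Extract introns with border dinucleotides
#'
#' Builds one record per intron of each transcript. Donor and acceptor are
#' the first and last two intronic bases in transcript orientation: on the
#' minus strand the stored sequence is the reverse complement of the genomic
#' slice, so the donor is always the biological 5' dinucleotide. Introns
#' shorter than `min_length` bases (donor and acceptor would overlap) are
#' excluded and counted in the `n_short` attribute. Introns with an N in a
#' border dinucleotide are flagged `ambiguous` and excluded from frequency
#' tables downstream.
#'
#' @param transcripts a single `transcript_model` or a list of them
#'   (typically representatives, see [representative_transcripts()]).
#' @param genome genome from [parse_genome()].
#' @param min_length minimum intron length in bases (default 4).
#' @return data.frame with one row per intron: `transcript_id`, `gene_id`,
#'   `intron_index` (1-based in transcript orientation), `chrom`, `start`,
#'   `end` (0-based half-open genomic), `strand`, `donor`, `acceptor`,
#'   `length`, `sequence`, `ambiguous`. Attribute `n_short` counts excluded
#'   sub-minimum introns.
#' @export
extract_introns <- function(transcripts, genome, min_length = 4) {
  if (inherits(transcripts, "transcript_model")) {
    transcripts <- list(transcripts)
  }
  rows <- lapply(transcripts, function(t) {
    iv <- intron_intervals(t)
    if (nrow(iv) == 0) return(NULL)
    data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
               intron_index = iv$intron_index, chrom = t$chrom,
               start = as.integer(iv$start), end = as.integer(iv$end),
               strand = t$strand, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    out <- data.frame(transcript_id = character(0), gene_id = character(0),
                      intron_index = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), donor = character(0),
                      acceptor = character(0), length = numeric(0),
                      sequence = character(0), ambiguous = logical(0))
    attr(out, "n_short") <- 0L
    return(out)
  }
  rows$length <- rows$end - rows$start
  short <- rows$length < min_length
  n_short <- sum(short)
  if (n_short > 0) {
    message(n_short, " intron(s) shorter than ", min_length,
            " bases excluded")
    rows <- rows[!short, , drop = FALSE]
  }
  if (nrow(rows) > 0) {
    rows$sequence <- substring(genome[rows$chrom], rows$start + 1, rows$end)
    minus <- rows$strand == "-"
    if (any(minus)) {
      rows$sequence[minus] <- reverse_complement(rows$sequence[minus])
    }
    rows$donor <- substr(rows$sequence, 1L, 2L)
    rows$acceptor <- substring(rows$sequence, rows$length - 1, rows$length)
    rows$ambiguous <- grepl("N", rows$donor, fixed = TRUE) |
      grepl("N", rows$acceptor, fixed = TRUE)
  } else {
    rows$sequence <- character(0)
    rows$donor <- character(0)
    rows$acceptor <- character(0)
    rows$ambiguous <- logical(0)
  }
  rows <- rows[order(rows$transcript_id, rows$intron_index), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_short") <- n_short
  rows
}

#' Classify a donor-acceptor combination
#'
#' GT-AG is the canonical combination; GC-AG and AT-AC are the two major
#' non-canonical combinations; every other dinucleotide pair is minor
#' non-canonical. Pairs containing N are `ambiguous` and are excluded from
#' frequency normalisation downstream.
#'
#' @param donor,acceptor character vectors of length-2 dinucleotides over
#'   A/C/G/T/N (recycled to a common length).
#' @return character vector with values `canonical`, `major_noncanonical`,
#'   `minor_noncanonical` or `ambiguous`.
#' @export
classify_combination <- function(donor, acceptor) {
  n <- max(length(donor), length(acceptor))
  donor <- rep_len(toupper(donor), n)
  acceptor <- rep_len(toupper(acceptor), n)
  if (any(nchar(donor) != 2) || any(nchar(acceptor) != 2)) {
    stop("donor and acceptor must be dinucleotides")
  }
  if (any(grepl("[^ACGTN]", c(donor, acceptor)))) {
    stop("dinucleotides restricted to the A/C/G/T/N alphabet")
  }
  combo <- paste(donor, acceptor, sep = "-")
  out <- rep("minor_noncanonical", n)
  out[combo == "GT-AG"] <- "canonical"
  out[combo %in% c("GC-AG", "AT-AC")] <- "major_noncanonical"
  out[grepl("N", combo, fixed = TRUE)] <- "ambiguous"
  out
}

#' Reverse complement of a combination string
#'
#' Maps a donor-acceptor combination to the combination an antisense
#' transcript over the same locus would show:
#' `revcomp(acceptor)-revcomp(donor)`. Applying it twice is the identity.
#' For example `CT-AC` maps to `GT-AG`, which is why canonical antisense
#' transcripts appear as CT-AC on the annotated strand.
#'
#' @param combo character vector of `"XX-YY"` combination strings.
#' @return character vector of combination strings.
#' @export
reverse_complement_combination <- function(combo) {
  parts <- strsplit(combo, "-", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed combination string: ",
                     paste(combo[bad], collapse = ", "))
  donor <- vapply(parts, `[[`, character(1), 1)
  acceptor <- vapply(parts, `[[`, character(1), 2)
  paste(reverse_complement(acceptor), reverse_complement(donor), sep = "-")
}

#' Tabulate splice-site combinations of a species
#'
#' Counts and normalises all donor-acceptor combinations over a set of
#' introns from representative transcripts. Ambiguous records (N in a
#' border dinucleotide) are excluded from the total so that they cannot
#' create phantom minor combinations.
#'
#' @param introns data.frame from [extract_introns()].
#' @param species_id optional species label stored as an attribute.
#' @return data.frame (`combination`, `count`, `frequency`, `class`), sorted
#'   by decreasing count then combination, with attributes `species_id`,
#'   `total` and `n_ambiguous`. With no unambiguous intron the table has
#'   zero rows, `total` 0 and attribute `undefined_frequencies = TRUE`.
#' @export
combination_table <- function(introns, species_id = NA_character_) {
  keep <- introns[!introns$ambiguous, , drop = FALSE]
  n_ambiguous <- nrow(introns) - nrow(keep)
  if (nrow(keep) == 0) {
    warning("no unambiguous introns; frequencies undefined")
    out <- data.frame(combination = character(0), count = integer(0),
                      frequency = numeric(0), class = character(0))
    attr(out, "species_id") <- species_id
    attr(out, "total") <- 0L
    attr(out, "n_ambiguous") <- n_ambiguous
    attr(out, "undefined_frequencies") <- TRUE
    return(out)
  }
  combo <- paste(keep$donor, keep$acceptor, sep = "-")
  counts <- table(combo)
  out <- data.frame(combination = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  total <- sum(out$count)
  out$frequency <- out$count / total
  parts <- strsplit(out$combination, "-", fixed = TRUE)
  out$class <- classify_combination(vapply(parts, `[[`, character(1), 1),
                                    vapply(parts, `[[`, character(1), 2))
  rownames(out) <- NULL
  attr(out, "species_id") <- species_id
  attr(out, "total") <- total
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' GC content of a combination's four border bases
#'
#' @param combo character vector of `"XX-YY"` combination strings.
#' @return numeric vector of fractions (number of G/C among the 4 border
#'   bases divided by 4). AT-AC, for instance, has GC content 0.25.
#' @export
combination_gc <- function(combo) {
  bases <- gsub("-", "", combo, fixed = TRUE)
  if (any(nchar(bases) != 4)) stop("malformed combination string")
  (nchar(gsub("[^GC]", "", bases))) / 4
}

#' Occurrence-weighted GC content of a species' splice sites
#'
#' Each combination's border GC content weighted by its count:
#' `sum(count * combination_gc) / total`.
#'
#' @param table a [combination_table()].
#' @return single fraction; `NA` with a warning when the table is empty.
#' @export
weighted_splice_gc <- function(table) {
  total <- attr(table, "total")
  if (is.null(total) || total == 0) {
    warning("combination table has total 0; weighted GC undefined")
    return(NA_real_)
  }
  sum(table$count * combination_gc(table$combination)) / total
}

#' Position frequency matrix around splice sites
#'
#' Counts bases at a window of exonic and intronic positions around the 5'
#' (donor) or 3' (acceptor) splice site, in transcript orientation. The
#' intronic window includes the terminal dinucleotide, so with the default
#' width of 7 the donor occupies intronic positions 1-2. Windows truncated
#' by sequence ends contribute only to the columns they cover; per-column
#' denominators are tracked.
#'
#' @param introns data.frame from [extract_introns()].
#' @param genome genome from [parse_genome()].
#' @param site `"5prime"` or `"3prime"`.
#' @param exonic,intronic window widths in bases (defaults 7 and 7).
#' @return object of class `flank_profile`: list with `site`, `counts`
#'   (5 x (exonic+intronic) matrix, rows A/C/G/T/N; columns named
#'   `E7...E1 | I1...I7` for the 5' site and `I7...I1 | E1...E7` for the 3'
#'   site), `denom` (per-column contributing introns) and `n`.
#' @export
flank_profile <- function(introns, genome, site = c("5prime", "3prime"),
                          exonic = 7, intronic = 7) {
  site <- match.arg(site)
  w <- exonic + intronic
  n <- nrow(introns)
  plus <- introns$strand == "+"
  # genomic window, 0-based half-open; orientation fixed afterwards
  if (site == "5prime") {
    ws <- ifelse(plus, introns$start - exonic, introns$end - intronic)
    we <- ifelse(plus, introns$start + intronic, introns$end + exonic)
  } else {
    ws <- ifelse(plus, introns$end - intronic, introns$start - exonic)
    we <- ifelse(plus, introns$end + exonic, introns$start + intronic)
  }
  chrom_len <- nchar(genome)[introns$chrom]
  cs <- pmax(ws, 0)
  ce <- pmin(we, chrom_len)
  seqs <- substring(genome[introns$chrom], cs + 1, ce)
  # pad truncated windows so every string has length w, then orient
  left_pad <- cs - ws
  right_pad <- we - ce
  seqs <- paste0(strrep(".", left_pad), seqs, strrep(".", right_pad))
  minus <- !plus
  if (any(minus)) {
    padded <- seqs[minus]
    # revcomp treating pads separately (pads swap ends on reversal)
    core <- gsub("\\.", "", padded)
    lp <- left_pad[minus]
    rp <- right_pad[minus]
    seqs[minus] <- paste0(strrep(".", rp), reverse_complement(core),
                          strrep(".", lp))
  }
  counts <- matrix(0L, nrow = 5, ncol = w,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  denom <- integer(w)
  for (j in seq_len(w)) {
    col <- substr(seqs, j, j)
    col <- col[col != "."]
    denom[j] <- length(col)
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    counts[, j] <- as.integer(tab)
  }
  colnames(counts) <- if (site == "5prime") {
    c(paste0("E", rev(seq_len(exonic))), paste0("I", seq_len(intronic)))
  } else {
    c(paste0("I", rev(seq_len(intronic))), paste0("E", seq_len(exonic)))
  }
  structure(list(site = site, counts = counts, denom = denom, n = n),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf("<flank_profile> %s site, %d introns\n", x$site, x$n))
  print(x$counts)
  invisible(x)
}

#' Write a combination table as TSV
#'
#' @param table a [combination_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combination_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a flank profile as a TSV matrix
#'
#' @param profile a [flank_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flank_profile <- function(profile, path) {
  m <- profile$counts
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export introns as BED6
#'
#' 0-based half-open intervals with the combination in the name column.
#'
#' @param introns data.frame from [extract_introns()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
introns_to_bed <- function(introns, path) {
  bed <- data.frame(chrom = introns$chrom,
                    start = format(introns$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(introns$end, scientific = FALSE,
                                 trim = TRUE),
                    name = paste0(introns$transcript_id, ".intron",
                                  introns$intron_index, ".",
                                  introns$donor, "-", introns$acceptor),
                    score = 0L,
                    strand = introns$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-flip a genome and its transcript models
#'
#' Replaces every chromosome by its reverse complement and remaps all
#' transcript coordinates accordingly, flipping strands. Extraction results
#' are invariant under this transformation, which makes it a useful
#' consistency check on strand handling.
#'
#' @param genome genome from [parse_genome()].
#' @param transcripts list of `transcript_model` objects.
#' @return list with elements `genome` and `transcripts`.
#' @export
strand_flip <- function(genome, transcripts) {
  flipped <- reverse_complement(genome)
  names(flipped) <- names(genome)
  lens <- nchar(genome)
  tr <- lapply(transcripts, function(t) {
    L <- lens[[t$chrom]]
    flip <- function(m) {
      if (nrow(m) == 0) return(m)
      cbind(start = L - m[, 2], end = L - m[, 1])
    }
    transcript_model(t$transcript_id, t$gene_id, t$chrom,
                     if (t$strand == "+") "-" else "+",
                     flip(t$exons),
                     if (nrow(t$cds)) flip(t$cds) else NULL)
  })
  names(tr) <- names(transcripts)
  list(genome = flipped, transcripts = tr)
}
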