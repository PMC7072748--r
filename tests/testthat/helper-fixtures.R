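# In-code fixtures and independent brute-force oracles.

write_fasta <- function(genome, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(genome), "\n", genome), path)
  path
}

# a minimal GFF3 for hand-built transcripts (1-based inclusive coords in)
write_gff3_lines <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# all 256 donor-acceptor combinations
all_combinations <- function() {
  b <- c("A", "C", "G", "T")
  di <- as.vector(outer(b, b, paste0))
  as.vector(outer(di, di, function(x, y) paste(x, y, sep = "-")))
}

# brute-force global alignment score by exhaustive recursion;
# independent of the DP implementation
brute_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      s <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(va)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(vb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# brute-force retention-frame check: literal scan of every codon window
brute_frame_check <- function(seq, offset) {
  len <- nchar(seq)
  if (len %% 3 != 0) return(FALSE)
  start <- (3 - offset %% 3) %% 3 + 1
  while (start + 2 <= len) {
    if (substr(seq, start, start + 2) %in% c("TAA", "TAG", "TGA")) {
      return(FALSE)
    }
    start <- start + 3
  }
  TRUE
}

# hand-built two-exon plus-strand gene: exon1 GTAAGT...TTCAG intron exon2
toy_two_exon <- function() {
  exon1 <- "ATGGCCAAA"                   # 9 bases: 0-9
  intron <- "GTAAGTCCCCCCTTTCAG"         # 18 bases: 9-27
  exon2 <- "GGGTTTTAA"                   # 9 bases: 27-36
  genome <- c(chr1 = paste0(exon1, intron, exon2))
  t <- transcript_model("t1", "g1", "chr1", "+",
                        rbind(c(0, 9), c(27, 36)),
                        rbind(c(0, 9), c(27, 36)))
  list(genome = genome, transcript = t, intron_seq = intron)
}

# an introns data.frame row built directly (for unit tests that do not
# need a genome)
make_intron <- function(chrom = "chr1", start, end, strand = "+",
                        donor = "GT", acceptor = "AG",
                        transcript_id = "t1", gene_id = "g1",
                        intron_index = 1L, sequence = NULL) {
  len <- end - start
  if (is.null(sequence)) {
    core <- strrep("C", len - 4)
    sequence <- paste0(donor, core, acceptor)
  }
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             intron_index = intron_index, chrom = chrom, start = start,
             end = end, strand = strand, donor = donor,
             acceptor = acceptor, length = len, sequence = sequence,
             ambiguous = grepl("N", paste0(donor, acceptor)))
}

# a coverage track built directly from per-chromosome depth vectors
make_track <- function(depth_list, junctions = NULL) {
  if (is.null(junctions)) {
    junctions <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), reads = numeric(0))
  }
  structure(list(depth = depth_list, junctions = junctions),
            class = "coverage_track")
}

# combination_string built directly from a combo vector
make_combo_string <- function(combos, codebook, transcript_id = "q",
                              species_id = "sp") {
  rare <- attr(codebook, "rare_symbol")
  syms <- unname(codebook[combos])
  syms[is.na(syms)] <- rare
  structure(list(transcript_id = transcript_id, species_id = species_id,
                 symbols = paste(syms, collapse = ""), combos = combos,
                 codebook = codebook),
            class = "combination_string")
}
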