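test_that("parse_genome normalises case and ambiguity codes", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "acgt"), p)
  expect_identical(parse_genome(p), c(chr1 = "ACGT"))

  writeLines(c(">c", "ACRT"), p)
  expect_identical(parse_genome(p), c(c = "ACNT"))

  writeLines(c(">a desc words", "ACGT"), p)
  expect_identical(names(parse_genome(p)), "a")
})

test_that("parse_genome rejects duplicates and empty files", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "AAAA", ">x", "CCCC"), p)
  expect_error(parse_genome(p), "duplicate")
  writeLines(character(0), p)
  expect_error(parse_genome(p))
})

test_that("parse_annotation builds transcript models with converted coordinates", {
  genome <- c(chr1 = strrep("ACGT", 30))  # 120 bases
  gff <- write_gff3_lines(c(
    "chr1\tsrc\tgene\t11\t100\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t11\t100\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t61\t100\t.\t-\t.\tID=t1.e1;Parent=t1",
    "chr1\tsrc\texon\t11\t30\t.\t-\t.\tID=t1.e2;Parent=t1",
    "chr1\tsrc\tCDS\t11\t30\t.\t-\t0\tID=t1.c1;Parent=t1",
    "chr1\tsrc\tgene\t101\t110\t.\t+\t.\tID=g2",
    "chr1\tsrc\tmRNA\t101\t110\t.\t+\t.\tID=t2;Parent=g2",
    "chr1\tsrc\texon\t101\t110\t.\t+\t.\tID=t2.e1;Parent=t2"
  ))
  tx <- parse_annotation(gff, genome)
  expect_named(tx, c("t1", "t2"))
  # minus-strand exons still sorted by genomic start, 0-based half-open
  expect_equal(unname(tx$t1$exons), rbind(c(10, 30), c(60, 100)))
  expect_identical(tx$t1$strand, "-")
  expect_equal(unname(tx$t1$cds), rbind(c(10, 30)))
  # single-exon transcript has no introns downstream
  expect_equal(nrow(extract_introns(tx$t2, genome)), 0)
})

test_that("parse_annotation rejects orphan and out-of-bounds features", {
  genome <- c(chr1 = strrep("A", 50))
  gff <- write_gff3_lines(c(
    "chr1\tsrc\tmRNA\t1\t40\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t1\t40\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tID=zz.e1;Parent=ghost"
  ))
  expect_warning(tx <- parse_annotation(gff, genome), "Parent")
  expect_named(tx, "t1")

  gff2 <- write_gff3_lines(c(
    "chr1\tsrc\tmRNA\t1\t60\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t1\t60\t.\t+\t.\tID=t1.e1;Parent=t1"
  ))
  expect_warning(tx2 <- parse_annotation(gff2, genome), "bounds")
  expect_length(tx2, 0)
})

test_that("select_representative applies the CDS/exon/id tie-break chain", {
  mk <- function(id, cds_len, ex_len) {
    transcript_model(id, "g", "chr1", "+",
                     rbind(c(0, ex_len)),
                     if (cds_len > 0) rbind(c(0, cds_len)) else NULL)
  }
  one <- mk("t1", 300, 400)
  expect_identical(select_representative(list(one)), one)
  expect_identical(
    select_representative(list(mk("t1", 300, 400), mk("t2", 450, 450)))$
      transcript_id, "t2")
  # equal CDS -> longer exons win
  expect_identical(
    select_representative(list(mk("t1", 300, 350), mk("t2", 300, 500)))$
      transcript_id, "t2")
  # full tie -> lexicographically smallest id
  expect_identical(
    select_representative(list(mk("t2", 300, 400), mk("t1", 300, 400)))$
      transcript_id, "t1")
  expect_error(select_representative(list()), "empty")
  expect_error(select_representative(
    list(transcript_model("a", "g1", "c", "+", rbind(c(0, 5))),
         transcript_model("b", "g2", "c", "+", rbind(c(0, 5))))),
    "multiple genes")
})

test_that("extract_introns reads borders in transcript orientation", {
  toy <- toy_two_exon()
  introns <- extract_introns(toy$transcript, toy$genome)
  expect_equal(nrow(introns), 1)
  expect_identical(introns$donor, "GT")
  expect_identical(introns$acceptor, "AG")
  expect_identical(introns$sequence, toy$intron_seq)
  expect_equal(introns$length, 18)

  # same gene placed on the minus strand of the reverse-complemented
  # genome must yield identical donor/acceptor (strand oracle)
  L <- nchar(toy$genome[["chr1"]])
  rc_genome <- c(chr1 = reverse_complement(toy$genome[["chr1"]]))
  flip <- function(m) cbind(L - m[, 2], L - m[, 1])
  t_minus <- transcript_model("t1", "g1", "chr1", "-",
                              flip(toy$transcript$exons))
  introns_m <- extract_introns(t_minus, rc_genome)
  expect_identical(introns_m$donor, "GT")
  expect_identical(introns_m$acceptor, "AG")
  expect_identical(introns_m$sequence, toy$intron_seq)
})

test_that("extract_introns excludes short introns and flags N borders", {
  genome <- c(chr1 = paste0("AAAA", "GTA", "CCCC", "GTNNNNAG", "TTTT"))
  # exons 0-4, 7-11, 19-23: intron1 len 3 (short), intron2 len 8
  t <- transcript_model("t1", "g1", "chr1", "+",
                        rbind(c(0, 4), c(7, 11), c(19, 23)))
  expect_message(introns <- extract_introns(t, genome), "shorter")
  expect_equal(nrow(introns), 1)
  expect_equal(attr(introns, "n_short"), 1L)
  expect_identical(introns$donor, "GT")
  expect_identical(introns$acceptor, "AG")
  # interior Ns do not make the record ambiguous
  expect_false(introns$ambiguous)
})

test_that("N in a border dinucleotide marks the intron ambiguous", {
  genome <- c(chr1 = paste0("AAAA", "NTCCCCAG", "TTTT"))
  t <- transcript_model("t1", "g1", "chr1", "+", rbind(c(0, 4), c(12, 16)))
  introns <- extract_introns(t, genome)
  expect_true(introns$ambiguous)
  expect_warning(tab <- combination_table(introns), "undefined")
  expect_equal(attr(tab, "total"), 0L)
  expect_equal(attr(tab, "n_ambiguous"), 1L)
})

test_that("classify_combination partitions all 256 combinations", {
  expect_identical(classify_combination("GT", "AG"), "canonical")
  expect_identical(classify_combination("GC", "AG"), "major_noncanonical")
  expect_identical(classify_combination("AT", "AC"), "major_noncanonical")
  expect_identical(classify_combination("GA", "AG"), "minor_noncanonical")
  expect_identical(classify_combination("NT", "AG"), "ambiguous")

  combos <- all_combinations()
  cls <- classify_combination(substr(combos, 1, 2), substr(combos, 4, 5))
  expect_equal(sum(cls == "canonical"), 1)
  expect_equal(sum(cls == "major_noncanonical"), 2)
  expect_equal(sum(cls == "minor_noncanonical"), 253)
  expect_error(classify_combination("G", "AG"), "dinucleotide")
  expect_error(classify_combination("GX", "AG"), "alphabet")
})

test_that("reverse_complement_combination maps CT-AC to GT-AG and is an involution", {
  expect_identical(reverse_complement_combination("CT-AC"), "GT-AG")
  expect_identical(reverse_complement_combination("GT-AG"), "CT-AC")
  combos <- all_combinations()
  expect_identical(
    reverse_complement_combination(reverse_complement_combination(combos)),
    combos)
  expect_error(reverse_complement_combination("GTAG"), "malformed")
})

test_that("combination_table counts, normalises and classifies", {
  introns <- do.call(rbind, c(
    replicate(98, make_intron(start = 0, end = 20), simplify = FALSE),
    replicate(2, make_intron(start = 0, end = 20, donor = "GC"),
              simplify = FALSE)))
  tab <- combination_table(introns, species_id = "sp1")
  expect_equal(attr(tab, "total"), 100L)
  expect_equal(tab$frequency[tab$combination == "GT-AG"], 0.98)
  expect_equal(tab$frequency[tab$combination == "GC-AG"], 0.02)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
  expect_identical(attr(tab, "species_id"), "sp1")

  one <- combination_table(make_intron(start = 0, end = 20, donor = "AT",
                                       acceptor = "AC"))
  expect_equal(one$frequency, 1)
  expect_identical(one$class, "major_noncanonical")

  expect_warning(empty <- combination_table(make_intron(
    start = 0, end = 20)[0, ]), "undefined")
  expect_equal(attr(empty, "total"), 0L)
  expect_true(attr(empty, "undefined_frequencies"))
})

test_that("class label counts sum to the table total", {
  set.seed(42)
  combos <- sample(all_combinations(), 200, replace = TRUE)
  introns <- do.call(rbind, lapply(seq_along(combos), function(i) {
    make_intron(start = 0, end = 20, donor = substr(combos[i], 1, 2),
                acceptor = substr(combos[i], 4, 5), intron_index = i)
  }))
  tab <- combination_table(introns)
  expect_equal(sum(tab$count), attr(tab, "total"))
  expect_true(all(tab$class %in% c("canonical", "major_noncanonical",
                                   "minor_noncanonical")))
})

test_that("combination_gc counts G/C among the four border bases", {
  expect_equal(combination_gc("AT-AC"), 0.25)
  expect_equal(combination_gc("GC-GC"), 1.0)
  expect_equal(combination_gc("AT-AT"), 0.0)
  expect_equal(combination_gc(c("GT-AG", "CT-AC")), c(0.5, 0.5))
})

test_that("weighted_splice_gc equals the brute-force sum over records", {
  pure <- combination_table(do.call(rbind, replicate(
    10, make_intron(start = 0, end = 20), simplify = FALSE)))
  expect_equal(weighted_splice_gc(pure), 0.5)

  half <- combination_table(rbind(
    do.call(rbind, replicate(5, make_intron(start = 0, end = 20,
                                            donor = "AT", acceptor = "AC"),
                             simplify = FALSE)),
    do.call(rbind, replicate(5, make_intron(start = 0, end = 20,
                                            donor = "GC", acceptor = "GC"),
                             simplify = FALSE))))
  expect_equal(weighted_splice_gc(half), 0.625)

  set.seed(7)
  combos <- sample(all_combinations(), 300, replace = TRUE)
  introns <- do.call(rbind, lapply(combos, function(cc) {
    make_intron(start = 0, end = 20, donor = substr(cc, 1, 2),
                acceptor = substr(cc, 4, 5))
  }))
  tab <- combination_table(introns)
  oracle <- mean(vapply(combos, combination_gc, numeric(1)))
  expect_equal(weighted_splice_gc(tab), oracle, tolerance = 1e-12)
})

test_that("flank_profile columns agree with stored donor/acceptor", {
  spec <- synthetic_spec(seed = 3, n_genes = 40, preset = "custom",
                         mixture = c("GT-AG" = 1))
  m <- generate_species(spec)
  genome <- parse_genome(m$fasta)
  introns <- extract_introns(
    representative_transcripts(parse_annotation(m$gff3, genome)), genome)
  p5 <- flank_profile(introns, genome, "5prime")
  # intronic positions 1-2 of the 5' site are the donor: all G then all T
  expect_equal(p5$counts["G", "I1"], p5$denom[8])
  expect_equal(p5$counts["T", "I2"], p5$denom[9])
  p3 <- flank_profile(introns, genome, "3prime")
  expect_equal(p3$counts["A", "I2"], p3$denom[6])
  expect_equal(p3$counts["G", "I1"], p3$denom[7])
  # column sums equal the per-column denominators
  expect_equal(unname(colSums(p5$counts)), p5$denom)
  expect_equal(p5$n, nrow(introns))
})

test_that("flank_profile shows a planted exonic consensus and single-intron counts", {
  spec <- synthetic_spec(seed = 5, n_genes = 40, preset = "custom",
                         mixture = c("GA-AG" = 1),
                         donor_exon_context = "AG")
  m <- generate_species(spec)
  genome <- parse_genome(m$fasta)
  introns <- extract_introns(
    representative_transcripts(parse_annotation(m$gff3, genome)), genome)
  p5 <- flank_profile(introns, genome, "5prime")
  # planted upstream AG exonic context right before the GA donor
  expect_equal(p5$counts["A", "E2"], p5$denom[6])
  expect_equal(p5$counts["G", "E1"], p5$denom[7])
  expect_equal(p5$counts["G", "I1"], p5$denom[8])
  expect_equal(p5$counts["A", "I2"], p5$denom[9])

  single <- flank_profile(introns[1, ], genome, "5prime")
  expect_true(all(colSums(single$counts) == 1))
})

test_that("flank_profile truncation reduces per-column denominators", {
  # intron starting 3 bases into the chromosome: E7..E4 truncated
  genome <- c(chr1 = paste0("AAA", "GTCCCCCCAG", "TTTTTTTT"))
  t <- transcript_model("t1", "g1", "chr1", "+", rbind(c(0, 3), c(13, 21)))
  introns <- extract_introns(t, genome)
  p5 <- flank_profile(introns, genome, "5prime")
  expect_equal(p5$denom, c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
})

test_that("combination tables are invariant under a genome strand flip", {
  spec <- synthetic_spec(seed = 9, n_genes = 60, preset = "fungi",
                         mixture = c("GT-AG" = 0.8, "GC-AG" = 0.1,
                                     "GA-AG" = 0.1))
  m <- generate_species(spec)
  genome <- parse_genome(m$fasta)
  reps <- representative_transcripts(parse_annotation(m$gff3, genome))
  tab1 <- combination_table(extract_introns(reps, genome))
  fl <- strand_flip(genome, reps)
  tab2 <- combination_table(extract_introns(fl$transcripts, fl$genome))
  expect_identical(tab1$combination, tab2$combination)
  expect_identical(tab1$count, tab2$count)
})

test_that("intron records export to BED6 and tables to TSV", {
  toy <- toy_two_exon()
  introns <- extract_introns(toy$transcript, toy$genome)
  bed <- tempfile(fileext = ".bed")
  introns_to_bed(introns, bed)
  row <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(row[1:3], c("chr1", "9", "27"))
  expect_identical(row[6], "+")

  tsv <- tempfile(fileext = ".tsv")
  write_combination_table(combination_table(introns), tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(back$combination, "GT-AG")
  expect_equal(back$count, 1)
})
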