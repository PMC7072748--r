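#' Run the per-species splice-site analysis end to end
#'
#' Orchestrates the whole pipeline for one species: parse genome and
#' annotation, select representative transcripts, extract and classify
#' intron border dinucleotides, build flank profiles, and — when the
#' corresponding evidence files are given — validate splice sites against
#' coverage, compute usage, expression bins, frame summaries, variant
#' rates and the per-species summary row. Every table is written as TSV
#' into `outdir` together with a machine-readable JSON run log (package
#' version, thresholds, input checksums, record counts).
#'
#' @param fasta,gff3 required input paths.
#' @param coverage,junctions optional coverage evidence (BAM, or
#'   interval-depth TSV plus junction TSV). Without them the report is
#'   annotation-only (a warning is raised, support/usage tables are
#'   skipped).
#' @param counts optional featureCounts-style count table
#'   (`gene_id<TAB>count`, no header).
#' @param vcf optional variant file.
#' @param outdir output directory.
#' @param species_id label used in outputs.
#' @param min_reads,drop validation thresholds (defaults 3 reads, 20%
#'   drop).
#' @param flank_exonic,flank_intronic flank-profile window widths.
#' @param outlier_quantile FPKM outlier cutoff for expression bins.
#' @return invisibly, a list with all computed tables (`combination_table`,
#'   `introns`, `support`, `usage`, `frame`, `summary`, `variants`, ...).
#' @export
run_species <- function(fasta, gff3, coverage = NULL, junctions = NULL,
                        counts = NULL, vcf = NULL, outdir = "splicecomb_out",
                        species_id = "species", min_reads = 3, drop = 0.2,
                        flank_exonic = 7, flank_intronic = 7,
                        outlier_quantile = 0.99) {
  for (p in c(fasta, gff3)) {
    if (!file.exists(p)) stop("input file missing: ", p)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- parse_genome(fasta)
  transcripts <- parse_annotation(gff3, genome)
  reps <- representative_transcripts(transcripts)
  introns <- extract_introns(reps, genome)
  tab <- combination_table(introns, species_id = species_id)
  write_combination_table(tab, file.path(outdir, "combination_table.tsv"))
  introns_to_bed(introns, file.path(outdir, "introns.bed"))
  res <- list(genome = genome, transcripts = reps, introns = introns,
              combination_table = tab)

  for (site in c("5prime", "3prime")) {
    prof <- flank_profile(introns[!introns$ambiguous, , drop = FALSE],
                          genome, site, flank_exonic, flank_intronic)
    write_flank_profile(prof, file.path(outdir,
                                        paste0("flank_", site, ".tsv")))
    res[[paste0("flank_", site)]] <- prof
  }

  res$frame <- frame_summary(introns, reps, by = "class")
  utils::write.table(res$frame, file.path(outdir, "frame_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(coverage)) {
    track <- load_coverage(coverage, genome, junctions)
    res$support <- validate_splice_sites(introns, track,
                                         min_reads = min_reads,
                                         drop = drop)
    utils::write.table(res$support, file.path(outdir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$usage <- splice_usage(introns, track)
    utils::write.table(res$usage, file.path(outdir, "usage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(counts)) {
      cnt <- utils::read.table(counts, sep = "\t", header = FALSE,
                               col.names = c("gene_id", "count"))
      tx_len <- vapply(reps, function(t) sum(t$exons[, 2] - t$exons[, 1]),
                       numeric(1))
      gene_of <- vapply(reps, `[[`, character(1), "gene_id")
      expr <- data.frame(gene_id = gene_of,
                         transcript_length = unname(tx_len))
      expr$read_count <- cnt$count[match(expr$gene_id, cnt$gene_id)]
      expr <- expr[!is.na(expr$read_count), , drop = FALSE]
      expr$fpkm <- fpkm(expr$read_count, expr$transcript_length,
                        max(sum(expr$read_count), 1))
      cls <- gene_classes(introns)
      expr <- merge(expr, cls, by = "gene_id")
      res$expression <- expr
      res$expression_bins <- expression_bins(
        expr, outlier_quantile = outlier_quantile)
      utils::write.table(res$expression_bins,
                         file.path(outdir, "expression_bins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$isoform <- isoform_presence(
        introns[!introns$ambiguous, , drop = FALSE], track,
        expr[, c("gene_id", "read_count", "transcript_length")])
      utils::write.table(res$isoform, file.path(outdir, "isoform.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    warning("no coverage evidence supplied; annotation-only report")
  }

  if (!is.null(vcf)) {
    variants <- parse_vcf(vcf)
    res$variant_rates <- splice_variant_rates(
      variants, introns[!introns$ambiguous, , drop = FALSE],
      exonic_background(reps))
    utils::write.table(
      as.data.frame(res$variant_rates),
      file.path(outdir, "variant_rates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  res$summary <- species_summary(genome, introns, tab,
                                 n_genes = length(reps),
                                 species_id = species_id)
  utils::write.table(res$summary, file.path(outdir, "species_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- c(fasta = fasta, gff3 = gff3, coverage = coverage,
              junctions = junctions, counts = counts, vcf = vcf)
  log <- list(
    package = "splicecomb",
    version = as.character(utils::packageVersion("splicecomb")),
    species_id = species_id,
    thresholds = list(min_reads = min_reads, drop = drop,
                      flank_exonic = flank_exonic,
                      flank_intronic = flank_intronic,
                      outlier_quantile = outlier_quantile),
    inputs = as.list(unname(Map(function(n, p) {
      list(role = n, path = p, md5 = unname(tools::md5sum(p)))
    }, names(inputs), inputs))),
    records = list(transcripts = length(transcripts),
                   genes = length(reps), introns = nrow(introns),
                   combinations = nrow(tab))
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
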