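#' Specification for a synthetic species
#'
#' Collects every knob of the synthetic-data generator: gene and intron
#' structure, the splice-site combination mixture, GC target, coverage and
#' noise model, retention / antisense / minor-isoform fractions, variant
#' rates and the expression effect for genes carrying non-canonical
#' splice sites. Two kingdom presets reproduce typical genome properties:
#' `"fungi"` (1.49 introns per gene, GC 0.471, short introns) and
#' `"animal"` (6.95 introns per gene, GC 0.394, longer introns).
#'
#' @param seed integer RNG seed; the whole emitted dataset is a
#'   deterministic function of the spec.
#' @param n_genes number of genes.
#' @param preset `"custom"`, `"animal"` or `"fungi"`; presets fill
#'   `mean_introns`, `gc` and `intron_length_mean` unless overridden.
#' @param mean_introns mean introns per gene (exon count is
#'   1 + Poisson(`mean_introns`)).
#' @param intron_length_mean,intron_length_min intron length model: a
#'   shifted geometric with this mean, at least `intron_length_min`
#'   (default 20) bases.
#' @param exon_length_mean,exon_length_min exon length model (shifted
#'   geometric).
#' @param mixture named probability vector over `"XX-YY"` combinations,
#'   summing to 1.
#' @param gc exonic/intronic GC target in `[0, 1]`.
#' @param spacer intergenic spacer length in bases.
#' @param genes_per_chromosome packing of genes onto chromosomes.
#' @param depth mean exonic read depth for [simulate_coverage()].
#' @param noise `"poisson"` or `"none"` (noise-free depth).
#' @param retained_fraction fraction of introns retained (unspliced).
#' @param antisense_fraction fraction of genes annotated on the wrong
#'   strand, so a true GT-AG intron appears as CT-AC on the annotated
#'   strand.
#' @param minor_isoform_fraction fraction of genes in which one intron
#'   belongs to a minor isoform only.
#' @param minor_isoform_freq relative abundance of that minor isoform.
#' @param variant_rate_splice,variant_rate_background per-base Bernoulli
#'   variant rates for [simulate_variants()].
#' @param expression_sdlog log-normal sd of the per-gene expression
#'   multiplier (0 = all genes equal).
#' @param noncanonical_expression_fc fold change of the expression
#'   multiplier for genes carrying at least one non-canonical combination.
#' @param donor_exon_context optional string planted at the 3' end of
#'   every exon that precedes an intron (exonic upstream context of the
#'   donor), e.g. `"AG"`.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 100L,
                           preset = c("custom", "animal", "fungi"),
                           mean_introns = NULL,
                           intron_length_mean = NULL,
                           intron_length_min = 20L,
                           exon_length_mean = 150L,
                           exon_length_min = 30L,
                           mixture = c("GT-AG" = 0.98, "GC-AG" = 0.015,
                                       "AT-AC" = 0.005),
                           gc = NULL,
                           spacer = 200L,
                           genes_per_chromosome = 100L,
                           depth = 50,
                           noise = c("poisson", "none"),
                           retained_fraction = 0,
                           antisense_fraction = 0,
                           minor_isoform_fraction = 0,
                           minor_isoform_freq = 0.2,
                           variant_rate_splice = 0,
                           variant_rate_background = 0,
                           expression_sdlog = 0.5,
                           noncanonical_expression_fc = 2,
                           donor_exon_context = NULL) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  defaults <- switch(preset,
    animal = list(mean_introns = 6.95, gc = 0.394,
                  intron_length_mean = 120),
    fungi = list(mean_introns = 1.49, gc = 0.471,
                 intron_length_mean = 80),
    custom = list(mean_introns = 4, gc = 0.45, intron_length_mean = 100)
  )
  if (is.null(mean_introns)) mean_introns <- defaults$mean_introns
  if (is.null(gc)) gc <- defaults$gc
  if (is.null(intron_length_mean)) {
    intron_length_mean <- defaults$intron_length_mean
  }
  if (is.null(names(mixture)) ||
      !all(grepl("^[ACGT]{2}-[ACGT]{2}$", names(mixture)))) {
    stop("mixture names must be dinucleotide combinations like 'GT-AG'")
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  fracs <- c(retained_fraction, antisense_fraction, minor_isoform_fraction,
             minor_isoform_freq, variant_rate_splice,
             variant_rate_background, gc)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (intron_length_mean < intron_length_min) {
    stop("intron_length_mean must be >= intron_length_min")
  }
  if (intron_length_min < 4) stop("intron_length_min must be >= 4")
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         preset = preset, mean_introns = mean_introns,
         intron_length_mean = intron_length_mean,
         intron_length_min = as.integer(intron_length_min),
         exon_length_mean = exon_length_mean,
         exon_length_min = as.integer(exon_length_min),
         mixture = mixture, gc = gc, spacer = as.integer(spacer),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         depth = depth, noise = noise,
         retained_fraction = retained_fraction,
         antisense_fraction = antisense_fraction,
         minor_isoform_fraction = minor_isoform_fraction,
         minor_isoform_freq = minor_isoform_freq,
         variant_rate_splice = variant_rate_splice,
         variant_rate_background = variant_rate_background,
         expression_sdlog = expression_sdlog,
         noncanonical_expression_fc = noncanonical_expression_fc,
         donor_exon_context = donor_exon_context),
    class = "synthetic_spec"
  )
}

# shifted geometric sampler: min + Geom with the requested mean
rgeom_shifted <- function(n, mean, min) {
  if (mean <= min) return(rep(as.integer(min), n))
  as.integer(min + stats::rgeom(n, 1 / (mean - min + 1)))
}

#' Generate a synthetic species with known ground truth
#'
#' Emits a genome FASTA and a GFF3 annotation whose intron borders carry
#' exactly the sampled donor-acceptor combinations, together with a truth
#' manifest recording every gene's strand, exon structure, per-intron
#' combination, retention status and isoform membership. Genes are placed
#' on both strands; antisense-artifact genes are annotated on the wrong
#' strand so their true GT-AG introns appear as the reverse-complement
#' combination. Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing; default a fresh
#'   temporary directory).
#' @return object of class `truth_manifest`: list with `fasta`, `gff3`
#'   (paths), `genome` (named character vector), `genes`, `introns`,
#'   `exons` (data.frames) and `spec`.
#' @export
generate_species <- function(spec, dir = tempfile("synthspecies")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  mix_names <- names(spec$mixture)
  donors <- substr(mix_names, 1, 2)
  acceptors <- substr(mix_names, 4, 5)
  base_prob <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
                 (1 - spec$gc) / 2)
  ctx <- spec$donor_exon_context
  if (!is.null(ctx)) ctx_chars <- strsplit(ctx, "")[[1]]

  genes <- vector("list", spec$n_genes)
  introns <- vector("list", spec$n_genes)
  exon_rows <- vector("list", spec$n_genes)
  n_chrom <- ceiling(spec$n_genes / spec$genes_per_chromosome)
  chrom_parts <- vector("list", n_chrom)
  chrom_offset <- integer(n_chrom)

  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%05d", g)
    tid <- sprintf("tx%05d", g)
    chrom_i <- ceiling(g / spec$genes_per_chromosome)
    chrom <- sprintf("chr%d", chrom_i)

    n_introns <- stats::rpois(1, spec$mean_introns)
    n_exons <- n_introns + 1
    exon_len <- rgeom_shifted(n_exons, spec$exon_length_mean,
                              spec$exon_length_min)
    intron_len <- rgeom_shifted(n_introns, spec$intron_length_mean,
                                spec$intron_length_min)
    combo_idx <- if (n_introns > 0) {
      sample.int(length(mix_names), n_introns, replace = TRUE,
                 prob = spec$mixture)
    } else integer(0)
    combos <- mix_names[combo_idx]
    retained <- stats::runif(n_introns) < spec$retained_fraction
    true_strand <- sample(c("+", "-"), 1)
    antisense <- n_introns > 0 &&
      stats::runif(1) < spec$antisense_fraction
    ann_strand <- if (antisense) setdiff(c("+", "-"), true_strand) else
      true_strand
    minor_gene <- n_introns > 0 &&
      stats::runif(1) < spec$minor_isoform_fraction
    minor_idx <- if (minor_gene) sample.int(n_introns, 1) else 0L

    # local (transcript-orientation) layout: exon1 intron1 exon2 ...
    seg_len <- integer(n_exons + n_introns)
    seg_len[seq(1, by = 2, length.out = n_exons)] <- exon_len
    if (n_introns > 0) {
      seg_len[seq(2, by = 2, length.out = n_introns)] <- intron_len
    }
    ends <- cumsum(seg_len)
    starts <- ends - seg_len  # 0-based
    gene_len <- ends[length(ends)]
    exon_local <- cbind(start = starts[seq(1, by = 2,
                                           length.out = n_exons)],
                        end = ends[seq(1, by = 2, length.out = n_exons)])
    intron_local <- if (n_introns > 0) {
      cbind(start = starts[seq(2, by = 2, length.out = n_introns)],
            end = ends[seq(2, by = 2, length.out = n_introns)])
    } else matrix(numeric(0), ncol = 2)

    vec <- sample(c("A", "C", "G", "T"), gene_len, replace = TRUE,
                  prob = base_prob)
    for (j in seq_len(n_introns)) {
      s <- intron_local[j, 1]
      e <- intron_local[j, 2]
      vec[(s + 1):(s + 2)] <- strsplit(donors[combo_idx[j]], "")[[1]]
      vec[(e - 1):e] <- strsplit(acceptors[combo_idx[j]], "")[[1]]
      if (!is.null(ctx) && s >= length(ctx_chars)) {
        vec[(s - length(ctx_chars) + 1):s] <- ctx_chars
      }
    }
    gene_seq <- paste(vec, collapse = "")

    # place on the chromosome (spacer before every gene)
    off <- chrom_offset[chrom_i] + spec$spacer
    placed <- if (true_strand == "+") gene_seq else
      reverse_complement(gene_seq)
    chrom_parts[[chrom_i]] <- c(chrom_parts[[chrom_i]],
                                random_seq(spec$spacer, spec$gc), placed)
    chrom_offset[chrom_i] <- off + gene_len

    to_genomic <- function(m) {
      if (nrow(m) == 0) return(m)
      if (true_strand == "+") {
        cbind(start = off + m[, 1], end = off + m[, 2])
      } else {
        cbind(start = off + gene_len - m[, 2],
              end = off + gene_len - m[, 1])
      }
    }
    exon_g <- to_genomic(exon_local)
    exon_g <- exon_g[order(exon_g[, 1]), , drop = FALSE]
    intron_g <- to_genomic(intron_local)

    if (n_introns > 0) {
      # index in annotated-transcript orientation
      ord <- order(intron_g[, 1])
      intron_g <- intron_g[ord, , drop = FALSE]
      meta_ord <- ord  # row j of intron_g is true intron meta_ord[j]
      ann_index <- if (ann_strand == "+") seq_len(n_introns) else
        rev(seq_len(n_introns))
      ann_combo <- combos[meta_ord]
      if (antisense) {
        ann_combo <- reverse_complement_combination(ann_combo)
      }
      introns[[g]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom,
        start = intron_g[, 1], end = intron_g[, 2], strand = ann_strand,
        intron_index = ann_index,
        true_combination = combos[meta_ord],
        combination = ann_combo,
        retained = retained[meta_ord],
        in_minor_isoform = (meta_ord == minor_idx)
      )
    }
    exon_rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom,
      start = exon_g[, 1], end = exon_g[, 2], strand = ann_strand
    )
    cls <- classify_combination(substr(combos, 1, 2), substr(combos, 4, 5))
    noncanon <- any(cls != "canonical")
    mult <- stats::rlnorm(
      1,
      meanlog = if (noncanon) log(spec$noncanonical_expression_fc) else 0,
      sdlog = spec$expression_sdlog
    )
    genes[[g]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom,
      strand = ann_strand, true_strand = true_strand,
      antisense = antisense, n_introns = n_introns,
      transcript_length = sum(exon_len),
      expression_multiplier = mult,
      gt_ag_only = !noncanon,
      has_gc_ag = any(combos == "GC-AG"),
      has_at_ac = any(combos == "AT-AC"),
      has_minor = any(cls == "minor_noncanonical")
    )
  }

  genome <- vapply(chrom_parts, paste, character(1), collapse = "")
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  genes <- do.call(rbind, genes)
  introns_df <- do.call(rbind, introns[!vapply(introns, is.null,
                                               logical(1))])
  if (is.null(introns_df)) {
    introns_df <- data.frame(gene_id = character(0),
                             transcript_id = character(0),
                             chrom = character(0), start = numeric(0),
                             end = numeric(0), strand = character(0),
                             intron_index = integer(0),
                             true_combination = character(0),
                             combination = character(0),
                             retained = logical(0),
                             in_minor_isoform = logical(0))
  }
  exons_df <- do.call(rbind, exon_rows)
  rownames(genes) <- rownames(introns_df) <- rownames(exons_df) <- NULL

  fasta <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
  gff3 <- file.path(dir, "annotation.gff3")
  write_gff3(genes, exons_df, gff3)

  structure(list(fasta = fasta, gff3 = gff3, genome = genome,
                 genes = genes, introns = introns_df, exons = exons_df,
                 spec = spec),
            class = "truth_manifest")
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf(
    "<truth_manifest> %d gene(s), %d intron(s) on %d chromosome(s)\n",
    nrow(x$genes), nrow(x$introns), length(x$genome)))
  invisible(x)
}

# plain-text GFF3 emitter for generated annotations (gene/mRNA/exon/CDS;
# CDS spans every exon). Coordinates converted to 1-based inclusive.
write_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gene_start <- tapply(exons$start, exons$gene_id, min)
  gene_end <- tapply(exons$end, exons$gene_id, max)
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    tid <- genes$transcript_id[i]
    ch <- genes$chrom[i]
    st <- genes$strand[i]
    gs <- gene_start[[gid]] + 1
    ge <- gene_end[[gid]]
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    lines <- c(
      lines,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ch, gs, ge, st,
              gid),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", ch,
              gs, ge, st, tid, gid),
      sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              ch, ex$start + 1, ex$end, st, tid, seq_len(nrow(ex)), tid),
      sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              ch, ex$start + 1, ex$end, st, tid, seq_len(nrow(ex)), tid)
    )
  }
  writeLines(lines, con)
  invisible(path)
}

#' Simulate RNA-Seq coverage evidence for a synthetic species
#'
#' Per-base depth: exonic bases at the gene's depth (Poisson noise or
#' exact), spliced introns at zero, retained introns at exonic depth.
#' Junction-spanning read counts are proportional to the spliced fraction
#' (zero for retained introns). The two exonic bases flanking a
#' minor-isoform intron are scaled down to the minor-isoform frequency, as
#' is that intron's junction count. Also emits a featureCounts-style
#' per-gene fragment count table consistent with the depth
#' (`count = depth * transcript_length / 200`).
#'
#' @param manifest a `truth_manifest` from [generate_species()].
#' @param depth mean exonic depth (default from the manifest's spec).
#' @param noise `"poisson"` or `"none"` (default from the spec).
#' @param seed optional RNG seed for the noise.
#' @param dir optional directory; when given, writes `coverage.tsv`
#'   (run-length-encoded interval depth), `junctions.tsv` and
#'   `counts.tsv`.
#' @return list with `track` (a `coverage_track`), `counts` (data.frame
#'   `gene_id`, `count`), `total_assigned`, and file paths when `dir` is
#'   given.
#' @export
simulate_coverage <- function(manifest, depth = NULL, noise = NULL,
                              seed = NULL, dir = NULL) {
  stopifnot(inherits(manifest, "truth_manifest"))
  spec <- manifest$spec
  if (is.null(depth)) depth <- spec$depth
  if (is.null(noise)) noise <- spec$noise
  if (!is.null(seed)) set.seed(seed)
  depth_vecs <- lapply(nchar(manifest$genome), function(L) integer(L))
  jx_rows <- vector("list", nrow(manifest$genes))
  counts <- numeric(nrow(manifest$genes))

  fill <- function(vec, start, end, value, noisy) {
    if (end <= start) return(vec)
    idx <- (start + 1):end
    vec[idx] <- if (noisy) stats::rpois(length(idx), value) else
      as.integer(round(value))
    vec
  }

  for (i in seq_len(nrow(manifest$genes))) {
    g <- manifest$genes[i, ]
    d <- depth * g$expression_multiplier
    noisy <- noise == "poisson"
    ch <- g$chrom
    vec <- depth_vecs[[ch]]
    ex <- manifest$exons[manifest$exons$gene_id == g$gene_id, ,
                         drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      vec <- fill(vec, ex$start[k], ex$end[k], d, noisy)
    }
    intr <- manifest$introns[manifest$introns$gene_id == g$gene_id, ,
                             drop = FALSE]
    if (nrow(intr) > 0) {
      jreads <- numeric(nrow(intr))
      for (k in seq_len(nrow(intr))) {
        if (intr$retained[k]) {
          vec <- fill(vec, intr$start[k], intr$end[k], d, noisy)
          jreads[k] <- 0
        } else {
          dj <- if (intr$in_minor_isoform[k]) d * spec$minor_isoform_freq
            else d
          jreads[k] <- if (noisy) stats::rpois(1, dj) else round(dj)
          if (intr$in_minor_isoform[k]) {
            # flanking exonic bases carried by the minor isoform only
            for (p in c(intr$start[k] - 1, intr$end[k])) {
              if (p >= 0 && p < length(vec)) {
                vec[p + 1] <- if (noisy) stats::rpois(1, dj) else
                  as.integer(round(dj))
              }
            }
          }
        }
      }
      jx_rows[[i]] <- data.frame(chrom = ch, start = intr$start,
                                 end = intr$end, reads = jreads)
    }
    depth_vecs[[ch]] <- vec
    counts[i] <- round(d * g$transcript_length / 200)
  }
  jx <- do.call(rbind, jx_rows[!vapply(jx_rows, is.null, logical(1))])
  if (is.null(jx)) jx <- empty_junctions()
  jx <- jx[jx$reads > 0, , drop = FALSE]
  rownames(jx) <- NULL
  track <- new_coverage_track(depth_vecs, jx)
  counts_df <- data.frame(gene_id = manifest$genes$gene_id,
                          count = counts)
  out <- list(track = track, counts = counts_df,
              total_assigned = sum(counts))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$coverage_tsv <- file.path(dir, "coverage.tsv")
    out$junctions_tsv <- file.path(dir, "junctions.tsv")
    out$counts_tsv <- file.path(dir, "counts.tsv")
    write_coverage_tsv(track, out$coverage_tsv)
    utils::write.table(jx, out$junctions_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(counts_df, out$counts_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Write a coverage track as a run-length-encoded interval TSV
#'
#' Four columns (`chrom start end depth`, 0-based half-open), zero-depth
#' runs omitted; the format read back by [load_coverage()].
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$depth)) {
    r <- rle(track$depth[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep], ends[keep], r$values[keep],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Plant sequence variants at splice borders and in exonic background
#'
#' Independent Bernoulli placement per base: the four border bases of every
#' intron at `rate_splice`, every exonic base at `rate_background`. Writes
#' a VCF v4.2 file when `file` is given.
#'
#' @param manifest a `truth_manifest`.
#' @param rate_splice,rate_background per-base variant rates in `[0, 1]`
#'   (defaults from the manifest's spec).
#' @param seed optional RNG seed.
#' @param file optional output VCF path.
#' @return list with `variants` (data.frame `chrom`, `pos` 0-based,
#'   `origin` = `"splice"`/`"background"`) and `vcf` (path or `NULL`).
#' @export
simulate_variants <- function(manifest, rate_splice = NULL,
                              rate_background = NULL, seed = NULL,
                              file = NULL) {
  stopifnot(inherits(manifest, "truth_manifest"))
  spec <- manifest$spec
  if (is.null(rate_splice)) rate_splice <- spec$variant_rate_splice
  if (is.null(rate_background)) {
    rate_background <- spec$variant_rate_background
  }
  stopifnot(rate_splice >= 0, rate_splice <= 1,
            rate_background >= 0, rate_background <= 1)
  if (!is.null(seed)) set.seed(seed)
  intr <- manifest$introns
  border <- unique(data.frame(
    chrom = rep(intr$chrom, 4),
    pos = c(intr$start, intr$start + 1, intr$end - 2, intr$end - 1)
  ))
  ex <- manifest$exons
  bg <- unique(data.frame(
    chrom = rep(ex$chrom, ex$end - ex$start),
    pos = sequence(ex$end - ex$start, from = ex$start)
  ))
  pick <- function(df, rate) {
    if (nrow(df) == 0 || rate == 0) return(df[0, , drop = FALSE])
    df[stats::runif(nrow(df)) < rate, , drop = FALSE]
  }
  vs <- pick(border, rate_splice)
  vb <- pick(bg, rate_background)
  variants <- rbind(
    if (nrow(vs)) cbind(vs, origin = "splice") else NULL,
    if (nrow(vb)) cbind(vb, origin = "background") else NULL
  )
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), pos = numeric(0),
                           origin = character(0))
  }
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  vcf <- NULL
  if (!is.null(file)) {
    write_vcf(variants, manifest$genome, file)
    vcf <- file
  }
  list(variants = variants, vcf = vcf)
}

# plain-text VCF v4.2 emitter for planted variants
write_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", names(genome), ",length=",
                      nchar(genome), ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    ref <- substring(genome[variants$chrom], variants$pos + 1,
                     variants$pos + 1)
    alt <- chartr("ACGTN", "CGTAA", ref)
    writeLines(paste(variants$chrom, variants$pos + 1, ".", ref, alt,
                     "100", "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}
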