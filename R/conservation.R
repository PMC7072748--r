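#' Build a symbol codebook for combination strings
#'
#' Encodes splice-site combinations as single letters of the amino-acid
#' alphabet so per-transcript combination strings can be aligned like
#' peptide sequences. The 19 globally most frequent combinations receive
#' fixed distinct symbols and every other combination maps to the single
#' rare symbol `X`. GT-AG always maps to `G`, independent of the dataset,
#' so codebooks are comparable across species.
#'
#' @param counts named numeric vector of combination counts (e.g. from a
#'   [combination_table()]'s `count` column named by `combination`), pooled
#'   over the datasets to be compared.
#' @return named character vector combination -> symbol, with attribute
#'   `rare_symbol = "X"`.
#' @export
build_codebook <- function(counts) {
  counts <- counts[!grepl("N", names(counts), fixed = TRUE)]
  counts <- counts[names(counts) != "GT-AG"]
  # deterministic order: count desc, then lexicographic
  ord <- order(-counts, names(counts))
  top <- names(counts)[ord][seq_len(min(18, length(counts)))]
  letters18 <- c("A", "C", "D", "E", "F", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W")
  cb <- c("GT-AG" = "G",
          stats::setNames(letters18[seq_along(top)], top))
  attr(cb, "rare_symbol") <- "X"
  cb
}

#' Encode a transcript's introns as a combination string
#'
#' One symbol per intron, in transcript orientation, using a fixed
#' codebook. Intronless transcripts yield the empty string.
#'
#' @param introns data.frame from [extract_introns()] restricted to one
#'   transcript (ordered by `intron_index`).
#' @param codebook from [build_codebook()].
#' @param species_id optional label.
#' @return object of class `combination_string`: list with
#'   `transcript_id`, `species_id`, `symbols` (single string), `combos`
#'   (character vector) and `codebook`.
#' @export
encode_combinations <- function(introns, codebook,
                                species_id = NA_character_) {
  tid <- unique(introns$transcript_id)
  if (length(tid) > 1) stop("introns of multiple transcripts supplied")
  if (length(tid) == 0) tid <- NA_character_
  introns <- introns[order(introns$intron_index), , drop = FALSE]
  combos <- paste(introns$donor, introns$acceptor, sep = "-")
  if (nrow(introns) == 0) combos <- character(0)
  rare <- attr(codebook, "rare_symbol")
  syms <- unname(codebook[combos])
  syms[is.na(syms)] <- rare
  structure(list(transcript_id = tid, species_id = species_id,
                 symbols = paste(syms, collapse = ""), combos = combos,
                 codebook = codebook),
            class = "combination_string")
}

#' @export
print.combination_string <- function(x, ...) {
  cat(sprintf("<combination_string> %s [%s]: %s\n", x$transcript_id,
              x$species_id, if (nchar(x$symbols)) x$symbols else "(empty)"))
  invisible(x)
}

#' Global alignment of two combination strings
#'
#' Needleman-Wunsch global alignment on symbol strings with configurable
#' match/mismatch/gap scores and deterministic tie-breaking (diagonal move
#' preferred over a gap in `a`, preferred over a gap in `b`).
#'
#' @param a,b `combination_string` objects or plain character strings.
#' @param match,mismatch,gap scores (defaults +1, 0, -1).
#' @return list with `score`, `a_aln`, `b_aln` (aligned strings with `-`
#'   gaps) and `a_pos`, `b_pos` (per alignment column, the 1-based symbol
#'   index in the original string, `NA` at gaps).
#' @export
align_strings <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  sa <- if (inherits(a, "combination_string")) a$symbols else a
  sb <- if (inherits(b, "combination_string")) b$symbols else b
  va <- strsplit(sa, "")[[1]]
  vb <- strsplit(sb, "")[[1]]
  n <- length(va)
  m <- length(vb)
  S <- matrix(0, n + 1, m + 1)
  # 1 = diagonal, 2 = gap in a (consume b), 3 = gap in b (consume a)
  P <- matrix(0L, n + 1, m + 1)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  P[1, -1] <- 2L
  P[-1, 1] <- 3L
  for (i in seq_len(n)) {
    sub <- ifelse(va[i] == vb, match, mismatch)
    for (j in seq_len(m)) {
      diag <- S[i, j] + sub[j]
      up <- S[i, j + 1] + gap      # gap in b, consume a[i]
      left <- S[i + 1, j] + gap    # gap in a, consume b[j]
      best <- max(diag, left, up)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (diag == best) 1L else if (left == best) 2L
        else 3L
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  acol <- integer(0); bcol <- integer(0)
  while (i > 1 || j > 1) {
    move <- P[i, j]
    if (move == 1L) {
      acol <- c(i - 1, acol); bcol <- c(j - 1, bcol); i <- i - 1; j <- j - 1
    } else if (move == 2L) {
      acol <- c(NA, acol); bcol <- c(j - 1, bcol); j <- j - 1
    } else {
      acol <- c(i - 1, acol); bcol <- c(NA, bcol); i <- i - 1
    }
  }
  list(score = S[n + 1, m + 1],
       a_aln = paste(ifelse(is.na(acol), "-", va[acol]), collapse = ""),
       b_aln = paste(ifelse(is.na(bcol), "-", vb[bcol]), collapse = ""),
       a_pos = acol, b_pos = bcol)
}

#' Conservation counts at non-canonical query positions
#'
#' For every non-canonical intron position of a query transcript, aligns
#' the query combination string pairwise against each homolog and tallies
#' what sits at the homologous position: the identical combination, a
#' different non-canonical combination, or canonical GT-AG. Positions
#' aligned only to gaps are excluded from the partition and counted in
#' `n_gap`.
#'
#' @param query a `combination_string` with at least one non-canonical
#'   intron.
#' @param homologs list of `combination_string` objects (one best homolog
#'   per species).
#' @param ... scoring parameters passed to [align_strings()].
#' @return data.frame with one row per non-canonical query position:
#'   `position` (intron index), `combination`, `n_same`, `n_other_nc`,
#'   `n_canonical`, `n_gap`.
#' @export
conservation_counts <- function(query, homologs, ...) {
  nc_pos <- which(query$combos != "GT-AG")
  if (length(nc_pos) == 0) {
    stop("query transcript has no non-canonical intron")
  }
  out <- data.frame(position = nc_pos,
                    combination = query$combos[nc_pos],
                    n_same = 0L, n_other_nc = 0L, n_canonical = 0L,
                    n_gap = 0L)
  for (h in homologs) {
    aln <- align_strings(query, h, ...)
    for (r in seq_along(nc_pos)) {
      col <- which(!is.na(aln$a_pos) & aln$a_pos == nc_pos[r])
      hom_idx <- aln$b_pos[col]
      if (length(hom_idx) == 0 || is.na(hom_idx)) {
        out$n_gap[r] <- out$n_gap[r] + 1L
        next
      }
      hom_combo <- h$combos[hom_idx]
      if (hom_combo == out$combination[r]) {
        out$n_same[r] <- out$n_same[r] + 1L
      } else if (hom_combo == "GT-AG") {
        out$n_canonical[r] <- out$n_canonical[r] + 1L
      } else {
        out$n_other_nc[r] <- out$n_other_nc[r] + 1L
      }
    }
  }
  out
}
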