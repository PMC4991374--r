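# Degeneracy sets of the 15-letter IUPAC DNA alphabet.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define an IUPAC consensus motif
#'
#' @param name Label, e.g. `"DBE"` or `"DAE"`.
#' @param consensus Consensus string over the 15-letter IUPAC DNA alphabet
#'   (`A C G T R Y S W K M B D H V N`); upper-cased on input.
#' @return An object of class `iupac_motif`.
#' @examples
#' iupac_motif("DBE_loose", "RTAAAYA") # R = A/G, Y = C/T
#' @export
iupac_motif <- function(name, consensus) {
  consensus <- toupper(as.character(consensus)[1])
  if (is.na(consensus) || !nzchar(consensus)) {
    stop("consensus must be non-empty", call. = FALSE)
  }
  chars <- strsplit(consensus, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in consensus: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(name = as.character(name)[1], consensus = consensus),
            class = "iupac_motif")
}

#' Does a sequence base satisfy an IUPAC code?
#'
#' True iff `base` lies in the degeneracy set of `code` (e.g. `R` accepts
#' `A` or `G`). A sequence base `N` (unknown/masked) matches no code,
#' including consensus `N` — the conservative-unknown rule, which avoids
#' phantom hits in masked regions.
#'
#' @param base A sequence character in `A C G T N`.
#' @param code An IUPAC alphabet character.
#' @return Logical scalar.
#' @export
iupac_char_match <- function(base, code) {
  base <- toupper(as.character(base)[1])
  code <- toupper(as.character(code)[1])
  if (!base %in% c("A", "C", "G", "T", "N")) {
    stop("invalid sequence base: ", base, call. = FALSE)
  }
  if (!code %in% names(IUPAC_SETS)) {
    stop("invalid IUPAC code: ", code, call. = FALSE)
  }
  if (base == "N") return(FALSE)
  base %in% IUPAC_SETS[[code]]
}

#' Built-in motif definitions for the DAF-16 promoter elements
#'
#' The DAF-16 binding element (DBE) is scanned as the two orientation
#' words `GTAAACA` and `TGTTTAC`; the loose form replaces them with the
#' degenerate consensus `RTAAAYA` (R = A/G, Y = C/T) and its
#' reverse-orientation word `TRTTTAY`, so that every strict match is
#' also a loose match in either orientation. The DAF-16
#' associated element (DAE), recognized by the transcription factor
#' PQM-1, is `TGATAAG` / `CTTATCA`. Scanning is forward-strand only;
#' reverse-orientation detection comes from listing both orientation
#' words explicitly.
#'
#' @param loose If `TRUE`, return the degenerate DBE instead of the two
#'   strict orientation words.
#' @return A list of [iupac_motif()] objects.
#' @export
dbe_motifs <- function(loose = FALSE) {
  if (loose) {
    list(iupac_motif("DBE", "RTAAAYA"), iupac_motif("DBE", "TRTTTAY"))
  } else {
    list(iupac_motif("DBE", "GTAAACA"), iupac_motif("DBE", "TGTTTAC"))
  }
}

#' @rdname dbe_motifs
#' @export
dae_motifs <- function() {
  list(iupac_motif("DAE", "TGATAAG"), iupac_motif("DAE", "CTTATCA"))
}

clean_sequence <- function(seq, gene = "?") {
  seq <- toupper(gsub("\\s", "", seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (!nzchar(seq)) stop("empty sequence for gene ", gene, call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence for gene ", gene,
         " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  seq
}

#' Construct a promoter set
#'
#' A promoter here is the sequence window immediately upstream of a
#' gene's transcription start site (TSS), written 5' to 3' and ending at
#' the TSS; the nominal window is 1 kb.
#'
#' @param genes Character vector of gene identifiers (unique).
#' @param sequences Character vector of sequences over `A C G T N`
#'   (upper-cased; `U` mapped to `T`).
#' @param expected_length Nominal window length; records of a different
#'   length are kept but reported via a warning.
#' @return A `data.frame` of class `promoter_set` with columns `gene`,
#'   `sequence`, `length`.
#' @export
promoter_set <- function(genes, sequences, expected_length = 1000) {
  genes <- as.character(genes)
  if (length(genes) != length(sequences)) {
    stop("genes and sequences differ in length", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  sequences <- mapply(clean_sequence, as.character(sequences), genes,
                      USE.NAMES = FALSE)
  len <- nchar(sequences)
  off <- genes[len != expected_length]
  if (length(off) > 0) {
    warning(length(off), " promoter(s) differ from the nominal ",
            expected_length, " nt window: ",
            paste(utils::head(off, 5), collapse = ", "),
            if (length(off) > 5) ", ..." else "", call. = FALSE)
  }
  structure(data.frame(gene = genes, sequence = sequences, length = len,
                       stringsAsFactors = FALSE),
            class = c("promoter_set", "data.frame"))
}

#' Read promoter sequences from a FASTA file
#'
#' The first whitespace-delimited token of each record header is taken as
#' the gene identifier. Sequences are upper-cased, `U` is mapped to `T`,
#' and characters outside `A C G T N` are rejected. Records whose length
#' differs from `expected_length` are kept with a warning.
#'
#' @param path FASTA file path.
#' @inheritParams promoter_set
#' @return A [promoter_set()].
#' @export
read_promoter_fasta <- function(path, expected_length = 1000) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) {
                     stop("malformed FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1)
  promoter_set(ids, as.character(recs), expected_length = expected_length)
}

#' Write a promoter set as FASTA
#'
#' @param promoters A [promoter_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  seqs <- Biostrings::BStringSet(promoters$sequence)
  names(seqs) <- promoters$gene
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

# Positions (1-based, from the 5' end) where `word` pattern-matches `seq`
# under IUPAC degeneracy; sequence 'N' matches nothing. All overlapping
# matches are reported.
scan_one <- function(seq, consensus) {
  w <- nchar(consensus)
  L <- nchar(seq)
  if (w > L) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  codes <- strsplit(consensus, "")[[1]]
  n_win <- L - w + 1
  ok <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    ok <- ok & chars[j:(n_win + j - 1)] %in% IUPAC_SETS[[codes[j]]]
  }
  which(ok)
}

#' Scan promoters for IUPAC consensus motifs
#'
#' Every window position of every promoter is tested against every
#' motif on the forward strand; all (including overlapping) matches are
#' reported. `start` is the 1-based offset of the match's first base from
#' the 5' end of the supplied promoter sequence. A motif longer than a
#' sequence yields no hits for that sequence (with a warning), not an
#' error.
#'
#' @param promoters A [promoter_set()] (or a single sequence string,
#'   which is wrapped as gene `"seq1"`).
#' @param motifs A list of [iupac_motif()] objects (a single motif is
#'   accepted).
#' @return A `data.frame` with columns `gene`, `motif`, `word`, `start`,
#'   sorted by gene, then `start`, then `motif`.
#' @examples
#' p <- promoter_set("toy", "ACGTAAACATT", expected_length = 11)
#' scan_motifs(p, dbe_motifs())
#' @export
scan_motifs <- function(promoters, motifs) {
  if (is.character(promoters)) {
    promoters <- suppressWarnings(promoter_set("seq1", promoters))
  }
  stopifnot(inherits(promoters, "promoter_set"))
  if (inherits(motifs, "iupac_motif")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, logical(1), "iupac_motif")))
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    seq <- promoters$sequence[i]
    for (mo in motifs) {
      w <- nchar(mo$consensus)
      if (w > nchar(seq)) {
        warning("motif ", mo$name, " (", mo$consensus,
                ") longer than promoter ", promoters$gene[i],
                "; skipped", call. = FALSE)
        next
      }
      starts <- scan_one(seq, mo$consensus)
      if (length(starts) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = promoters$gene[i], motif = mo$name,
          word = substring(seq, starts, starts + w - 1),
          start = starts, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), motif = character(0),
                      word = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$gene, hits$start, hits$motif), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Convert a 5'-offset match position to distance upstream of the TSS
#'
#' Match positions are reported as 1-based offsets from the 5' end of the
#' promoter window. For a window of length `seq_length` ending at the
#' TSS, the equivalent distance from the TSS back to the 3' end of a
#' match of width `width` is `seq_length - start - width + 2`. The window
#' origin is a convention choice; both coordinates are offered.
#'
#' @param start 1-based match offset(s) from the window's 5' end.
#' @param width Motif width in nucleotides.
#' @param seq_length Promoter window length.
#' @return Distance(s) upstream of the TSS (1 = the base adjacent to the
#'   TSS).
#' @export
upstream_offset <- function(start, width, seq_length = 1000) {
  seq_length - start - width + 2
}

#' Classify genes by DBE/DAE promoter content
#'
#' A gene is DBE-positive iff its promoter has at least one hit for any
#' DBE motif (similarly DAE); the two flags assign each gene to one of
#' the categories `DBE_only`, `DAE_only`, `both`, `neither`.
#'
#' @param promoters A [promoter_set()].
#' @param dbe,dae Motif lists, defaulting to [dbe_motifs()] and
#'   [dae_motifs()]; an empty list disables that element.
#' @return An object of class `motif_classification`: list with `genes`
#'   (data frame `gene`, `dbe`, `dae`, `category`), `counts` (named
#'   vector over the four categories, summing to the number of genes),
#'   and `hits` (the full [scan_motifs()] table).
#' @export
classify_promoters <- function(promoters, dbe = dbe_motifs(),
                               dae = dae_motifs()) {
  stopifnot(inherits(promoters, "promoter_set"), nrow(promoters) > 0)
  hits <- scan_motifs(promoters, c(dbe, dae))
  dbe_names <- vapply(dbe, function(m) m$name, character(1))
  dae_names <- vapply(dae, function(m) m$name, character(1))
  has_dbe <- promoters$gene %in% hits$gene[hits$motif %in% dbe_names]
  has_dae <- promoters$gene %in% hits$gene[hits$motif %in% dae_names]
  category <- ifelse(has_dbe & has_dae, "both",
              ifelse(has_dbe, "DBE_only",
              ifelse(has_dae, "DAE_only", "neither")))
  genes <- data.frame(gene = promoters$gene, dbe = has_dbe, dae = has_dae,
                      category = category, stringsAsFactors = FALSE)
  counts <- vapply(c("DBE_only", "DAE_only", "both", "neither"),
                   function(cl) sum(category == cl), integer(1))
  structure(list(genes = genes, counts = counts, hits = hits),
            class = "motif_classification")
}

#' @export
print.motif_classification <- function(x, ...) {
  cat("motif classification of", nrow(x$genes), "genes:\n")
  cat(sprintf("  DBE_only %d  DAE_only %d  both %d  neither %d\n",
              x$counts[["DBE_only"]], x$counts[["DAE_only"]],
              x$counts[["both"]], x$counts[["neither"]]))
  invisible(x)
}

#' Format the genes carrying both elements as a compact report
#'
#' One line per gene with all of its DBE and DAE hits rendered as
#' `[word: position]` lists, the layout used to present co-regulated
#' promoters.
#'
#' @param classification A [classify_promoters()] result.
#' @return Character vector, one formatted line per `both` gene.
#' @export
format_both_report <- function(classification) {
  stopifnot(inherits(classification, "motif_classification"))
  both <- classification$genes$gene[classification$genes$category == "both"]
  vapply(both, function(g) {
    h <- classification$hits[classification$hits$gene == g, , drop = FALSE]
    fmt <- function(motif) {
      hh <- h[h$motif == motif, , drop = FALSE]
      paste0(sprintf("[%s: %d]", hh$word, hh$start), collapse = "")
    }
    paste0(g, "\t", fmt("DBE"), "\t", fmt("DAE"))
  }, character(1))
}

#' Write motif scan outputs as TSV
#'
#' `write_motif_hits()` writes the hit table (`gene`, `motif`, `word`,
#' `start`); `write_motif_classification()` writes the per-gene category
#' table (`gene`, `category`).
#'
#' @param hits A [scan_motifs()] data frame.
#' @param classification A [classify_promoters()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_motif_hits
#' @export
write_motif_classification <- function(classification, path) {
  stopifnot(inherits(classification, "motif_classification"))
  utils::write.table(classification$genes[, c("gene", "category")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
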