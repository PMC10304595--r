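#' Read sequences from a FASTA file
#'
#' Wraps Biostrings' FASTA reader and returns a [protein_set()] or
#' [nucleotide_set()]. Sequences are upper-cased; for protein input a single
#' trailing `*` stop character is stripped. Gzip-compressed files are accepted
#' by extension (`.gz`).
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return a `seq_set` with one record per FASTA entry, input order preserved.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("no records in ", path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(ss))
  if (alphabet == "protein") {
    seqs <- sub("\\*$", "", seqs)
    protein_set(id, seqs, description = desc)
  } else {
    nucleotide_set(id, seqs, description = desc)
  }
}

#' Write a `seq_set` to FASTA
#'
#' Lines wrap at 60 columns. `read_fasta()` after `write_fasta()` preserves
#' ids and residues exactly.
#'
#' @param x a `seq_set`.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  ss <- Biostrings::BStringSet(setNames(x$residues, hdr))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Six-frame translation of nucleotide contigs
#'
#' Translates every contig in all six reading frames with the standard genetic
#' code and reports all stop-to-stop open reading segments of at least
#' `min_len` residues. There is no start-codon requirement: partial
#' transcripts (TSA-style contigs) routinely truncate reading frames, so any
#' stop-free codon run is a candidate. Codons containing `N` translate to `X`.
#'
#' Coordinates are reported 1-based inclusive on the forward strand of the
#' parent contig (for negative frames the span still refers to forward-strand
#' positions).
#'
#' @param x a nucleotide `seq_set`.
#' @param min_len minimum peptide length to report (>= 1).
#' @return a protein `seq_set` with ids `<contig>|f<frame>|<start>-<end>`,
#'   plus columns `contig`, `start`, `end`.
#' @export
six_frame_translate <- function(x, min_len = 30L) {
  stopifnot(min_len >= 1L)
  out <- list()
  for (k in seq_len(nrow(x))) {
    contig <- x$id[k]
    bases <- x$residues[k]
    L <- nchar(bases)
    for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      strand_seq <- if (frame > 0) bases else revcomp(bases)
      off <- abs(frame) - 1L
      ncod <- (nchar(strand_seq) - off) %/% 3L
      if (ncod < 1L) next
      cod_seq <- substr(strand_seq, off + 1L, off + 3L * ncod)
      pep <- translate_codons(cod_seq)
      # split stop-to-stop; locate each segment in codon units
      segs <- stop_free_segments(pep)
      for (s in segs) {
        if (s$len < min_len) next
        # codon indices s$from..s$to (1-based) on the reading strand
        sb <- off + 3L * (s$from - 1L) + 1L
        se <- off + 3L * s$to
        if (frame > 0) { fs <- sb; fe <- se } else { fs <- L - se + 1L; fe <- L - sb + 1L }
        out[[length(out) + 1L]] <- data.frame(
          id = sprintf("%s|f%+d|%d-%d", contig, frame, fs, fe),
          description = "", residues = s$pep, source = "translated",
          frame = frame, contig = contig, start = fs, end = fe,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(id = character(), description = character(),
                      residues = character(), source = character(),
                      frame = integer(), contig = character(),
                      start = integer(), end = integer())
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("seq_set", "data.frame")
  attr(res, "alphabet") <- "protein"
  res
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_codons <- function(s) {
  dna <- Biostrings::DNAString(s)
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# split a peptide (with '*' stops) into stop-free runs, in codon coordinates
stop_free_segments <- function(pep) {
  parts <- strsplit(pep, "")[[1]]
  runs <- rle(parts == "*")
  segs <- list()
  pos <- 1L
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (!runs$values[r]) {
      seg <- substr(pep, pos, pos + len - 1L)
      segs[[length(segs) + 1L]] <- list(pep = seg, from = pos,
                                        to = pos + len - 1L, len = len)
    }
    pos <- pos + len
  }
  segs
}
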