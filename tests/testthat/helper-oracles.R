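# Independent brute-force oracles used across the suite.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# --- motif oracle: regex with lookahead, overlapping matches, 0-based starts
motif_regex <- function(pattern) {
  paste0(vapply(pattern, function(p) {
    if (identical(p, "any")) "." else paste0("[", paste(p, collapse = ""), "]")
  }, ""), collapse = "")
}

brute_motif_offsets <- function(seq, pattern) {
  rx <- paste0("(?=", motif_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# --- global affine alignment oracle: enumerate every alignment path
# gap of length k costs open + (k - 1) * ext
brute_align_score <- function(a, b, B, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, score + B[ca[i], cb[j]], "D")
    if (i <= length(ca))
      rec(i + 1L, j, score - if (last == "U") ext else open, "U")
    if (j <= length(cb))
      rec(i, j + 1L, score - if (last == "L") ext else open, "L")
  }
  rec(1L, 1L, 0, "")
  best
}

# --- bipartition set of an unrooted tree (canonical string form)
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- sort(attr(pp, "labels")[cl])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    other <- setdiff(tips, side)
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

brute_rf <- function(t1, t2) {
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- monophyly oracle: a group is a clade (after rooting on `out`) iff it is
# one side of some bipartition whose other side contains the outgroup, or a
# single leaf
brute_monophyletic <- function(tree, group, out) {
  if (length(group) == 1L) return(TRUE)
  grp <- paste(sort(group), collapse = ",")
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  n <- length(labels)
  for (cl in pp) {
    side <- sort(labels[cl])
    other <- sort(setdiff(labels, side))
    for (s in list(side, other)) {
      if (length(s) == 0L || length(s) == n) next
      if (paste(s, collapse = ",") == grp && !(out %in% s)) return(TRUE)
    }
  }
  FALSE
}

# --- six-frame ORF oracle: independent splitting with the standard code
brute_orfs <- function(bases, min_len) {
  code <- Biostrings::GENETIC_CODE
  tr1 <- function(codon) {
    if (grepl("N", codon)) "X" else unname(code[codon])
  }
  peps <- character(0)
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    s <- if (frame > 0) bases else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
    off <- abs(frame) - 1
    ncod <- (nchar(s) - off) %/% 3
    if (ncod < 1) next
    codons <- substring(s, off + 1 + 3 * (seq_len(ncod) - 1),
                        off + 3 * seq_len(ncod))
    aa <- vapply(codons, tr1, "")
    runs <- strsplit(paste(aa, collapse = ""), "\\*")[[1]]
    peps <- c(peps, runs[nchar(runs) >= min_len])
  }
  sort(peps)
}

# small convenience: seq_set row bind keeping class
bind_records <- function(...) {
  x <- rbind(...)
  class(x) <- c("seq_set", "data.frame")
  x
}
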