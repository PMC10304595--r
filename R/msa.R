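#' Progressive multiple sequence alignment
#'
#' Clustal-style progressive alignment: pairwise global alignments give an
#' identity distance matrix (`d = 1 - identity/100`), a UPGMA guide tree is
#' built from it, and groups are merged in guide-tree order by
#' profile-profile alignment. The profile-profile column score is the mean
#' pairwise substitution score over the two column populations (residue vs.
#' gap scores 0); new gaps pay the affine penalties of `params`.
#'
#' @param recs protein `seq_set` with at least two records and unique ids.
#' @param params an [alignment_params()].
#' @return list of class `msa_result`: `ids`, `rows` (named gapped strings in
#'   input order, equal length), `guide` (an `hclust`), `params`.
#' @export
progressive_msa <- function(recs, params = alignment_params()) {
  n <- nrow(recs)
  if (n < 2L) stop("need at least 2 records")
  if (anyDuplicated(recs$id)) stop("duplicate record ids")
  if (n == 2L) {
    pa <- global_align(recs[1, ], recs[2, ], params)
    rows <- setNames(pa$aligned, recs$id)
    return(structure(list(ids = recs$id, rows = rows, guide = NULL,
                          params = params), class = "msa_result"))
  }
  idm <- identity_matrix(recs, mode = "pairwise", params = params)
  D <- as.dist(1 - unclass(idm) / 100)
  guide <- hclust(D, method = "average")

  B <- extended_subst_matrix(params$matrix)
  groups <- lapply(seq_len(n), function(k)
    list(ids = recs$id[k], rows = recs$residues[k]))
  merged <- vector("list", nrow(guide$merge))
  for (s in seq_len(nrow(guide$merge))) {
    g1 <- pick_group(guide$merge[s, 1], groups, merged)
    g2 <- pick_group(guide$merge[s, 2], groups, merged)
    merged[[s]] <- merge_groups(g1, g2, B, params)
  }
  final <- merged[[length(merged)]]
  ord <- match(recs$id, final$ids)
  rows <- setNames(final$rows[ord], recs$id)
  structure(list(ids = recs$id, rows = rows, guide = guide, params = params),
            class = "msa_result")
}

pick_group <- function(idx, groups, merged) {
  if (idx < 0) groups[[-idx]] else merged[[idx]]
}

# substitution matrix extended with a neutral gap character
extended_subst_matrix <- function(name) {
  B <- get_subst_matrix(name)
  letters <- rownames(B)
  M <- matrix(0, length(letters) + 1L, length(letters) + 1L,
              dimnames = list(c(letters, "-"), c(letters, "-")))
  M[letters, letters] <- B
  M
}

group_counts <- function(rows, letters) {
  mat <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(mat)
  C <- matrix(0, L, length(letters), dimnames = list(NULL, letters))
  for (j in seq_len(L)) {
    t <- table(factor(mat[, j], levels = letters))
    C[j, ] <- as.numeric(t)
  }
  C
}

merge_groups <- function(g1, g2, B, params) {
  letters <- rownames(B)
  C1 <- group_counts(g1$rows, letters)
  C2 <- group_counts(g2$rows, letters)
  S <- (C1 %*% B %*% t(C2)) / (length(g1$rows) * length(g2$rows))
  res <- cpp_affine_global(S, params$gap_open, params$gap_extend)
  mv <- strsplit(res$moves, "")[[1]]
  r1 <- do.call(rbind, strsplit(g1$rows, ""))
  r2 <- do.call(rbind, strsplit(g2$rows, ""))
  i <- 0L; j <- 0L
  out1 <- matrix("", nrow(r1), length(mv))
  out2 <- matrix("", nrow(r2), length(mv))
  for (k in seq_along(mv)) {
    if (mv[k] != "L") { i <- i + 1L; out1[, k] <- r1[, i] } else out1[, k] <- "-"
    if (mv[k] != "U") { j <- j + 1L; out2[, k] <- r2[, j] } else out2[, k] <- "-"
  }
  list(ids = c(g1$ids, g2$ids),
       rows = c(apply(out1, 1, paste, collapse = ""),
                apply(out2, 1, paste, collapse = "")))
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("<msa_result> %d sequences, %d columns\n", length(x$rows),
              nchar(x$rows[1])))
  invisible(x)
}

#' Write an MSA as aligned FASTA or Clustal-style text
#' @param msa an `msa_result`.
#' @param path output path.
#' @param format `"fasta"` or `"clustal"`.
#' @export
write_msa <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(msa$rows)
    Biostrings::writeXStringSet(ss, path, width = 60L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL-style alignment (tpppscan)\n", con)
    L <- nchar(msa$rows[1])
    wid <- max(nchar(names(msa$rows))) + 2L
    for (from in seq(1L, L, by = 60L)) {
      to <- min(from + 59L, L)
      for (k in seq_along(msa$rows))
        writeLines(sprintf("%-*s%s", wid, names(msa$rows)[k],
                           substr(msa$rows[k], from, to)), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
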