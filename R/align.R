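blosum_cache <- new.env(parent = emptyenv())

get_subst_matrix <- function(name = "BLOSUM62") {
  if (!is.null(blosum_cache[[name]])) return(blosum_cache[[name]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  blosum_cache[[name]] <- m
  m
}

#' Alignment parameters
#'
#' Affine-gap scoring: a gap of length k costs `gap_open + (k-1)*gap_extend`.
#' @param matrix substitution matrix name (a Biostrings data set).
#' @param gap_open,gap_extend positive penalties, `gap_open >= gap_extend > 0`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

#' Trim residues N-terminal to the first domain hit
#'
#' Removes everything before the start of the supplied hit, the conventional
#' preprocessing before tree building so that variable N-terminal extensions
#' do not dominate the alignment. The id gains a `::trimmed` suffix.
#'
#' @param rec single-row protein `seq_set`.
#' @param first_hit one `domain_hits` row belonging to `rec`.
#' @return single-row protein `seq_set`.
#' @export
trim_to_domain <- function(rec, first_hit) {
  if (first_hit$protein_id[1] != rec$id[1])
    stop("hit does not belong to record '", rec$id[1], "'")
  res <- substr(rec$residues[1], first_hit$start[1] + 1L,
                nchar(rec$residues[1]))
  protein_set(paste0(rec$id[1], "::trimmed"), res,
              description = rec$description[1])
}

#' Optimal global pairwise alignment (Gotoh affine-gap DP)
#'
#' Needleman-Wunsch with affine gaps via the three-state Gotoh recursion;
#' the traceback is deterministic with tie order diagonal > up > left.
#'
#' @param a,b single-row protein `seq_set`s (or lists with `id`, `residues`).
#' @param params an [alignment_params()].
#' @return list of class `pairwise_alignment`: `ids`, `aligned` (two gapped
#'   strings), `score`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  ra <- a$residues[1]; rb <- b$residues[1]
  stopifnot(nzchar(ra), nzchar(rb))
  B <- get_subst_matrix(params$matrix)
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  S <- B[ca, cb, drop = FALSE]
  res <- cpp_affine_global(S, params$gap_open, params$gap_extend)
  mv <- strsplit(res$moves, "")[[1]]
  ai <- cumsum(mv != "L"); bi <- cumsum(mv != "U")
  row_a <- ifelse(mv == "L", "-", ca[ai])
  row_b <- ifelse(mv == "U", "-", cb[bi])
  structure(list(ids = c(a$id[1], b$id[1]),
                 aligned = c(paste(row_a, collapse = ""),
                             paste(row_b, collapse = "")),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s  score %.1f  identity %.2f%%\n",
              x$ids[1], x$ids[2], x$score, percent_identity(x)))
  cat(" ", x$aligned[1], "\n ", x$aligned[2], "\n")
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percent identity of two aligned rows
#'
#' `100 * identical columns / columns where both rows are non-gap`, rounded
#' half-up to two decimals. Columns where either row has a gap do not enter
#' the denominator. Alternative denominators (full alignment length; shorter
#' ungapped sequence) are available because the convention differs across
#' alignment tools.
#'
#' @param aln a `pairwise_alignment`, or a character vector of two equal-length
#'   gapped strings.
#' @param denominator `"both_ungapped"` (default), `"alignment_length"` or
#'   `"shorter_seq"`.
#' @return percentage in \[0, 100\].
#' @export
percent_identity <- function(aln, denominator = c("both_ungapped",
                                                  "alignment_length",
                                                  "shorter_seq")) {
  denominator <- match.arg(denominator)
  rows <- if (inherits(aln, "pairwise_alignment")) aln$aligned else aln
  stopifnot(length(rows) == 2L, nchar(rows[1]) == nchar(rows[2]))
  a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
  both <- a != "-" & b != "-"
  ident <- sum(both & a == b)
  den <- switch(denominator,
    both_ungapped = sum(both),
    alignment_length = length(a),
    shorter_seq = min(sum(a != "-"), sum(b != "-")))
  if (den == 0L) return(NA_real_)
  round_half_up(100 * ident / den, 2)
}
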