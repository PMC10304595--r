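#' @useDynLib tpppscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist hclust quantile rbinom rgeom rpois runif setNames
#' @importFrom utils head read.table write.table
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET <- c(AA20, "X")
NT_ALPHABET <- c("A", "C", "G", "T", "N")

#' Build a set of protein records
#'
#' A `seq_set` is the package's container for named sequences: a data frame
#' with columns `id`, `description`, `residues`, `source` and `frame`.
#' Sequences are upper-case amino-acid strings over the 20 standard residues
#' plus `X` for unknown. `source` records whether a sequence came straight
#' from a protein FASTA (`"protein"`) or from six-frame translation of a
#' nucleotide contig (`"translated"`, in which case `frame` is one of
#' -3..-1, 1..3).
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of amino-acid sequences.
#' @param description optional free-text descriptions.
#' @param source `"protein"` or `"translated"`, recycled.
#' @param frame integer frame for translated records, `NA` otherwise.
#' @return a data frame of class `seq_set`.
#' @export
protein_set <- function(id, residues, description = "", source = "protein",
                        frame = NA_integer_) {
  residues <- toupper(residues)
  x <- data.frame(id = as.character(id), description = description,
                  residues = residues, source = source, frame = as.integer(frame),
                  stringsAsFactors = FALSE)
  validate_seq_set(x, alphabet = "protein")
  class(x) <- c("seq_set", "data.frame")
  attr(x, "alphabet") <- "protein"
  x
}

#' @rdname protein_set
#' @param bases character vector of nucleotide sequences over A,C,G,T,N.
#' @export
nucleotide_set <- function(id, bases, description = "") {
  bases <- toupper(bases)
  x <- data.frame(id = as.character(id), description = description,
                  residues = bases, source = "nucleotide",
                  frame = NA_integer_, stringsAsFactors = FALSE)
  validate_seq_set(x, alphabet = "nucleotide")
  class(x) <- c("seq_set", "data.frame")
  attr(x, "alphabet") <- "nucleotide"
  x
}

validate_seq_set <- function(x, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (nrow(x) == 0L) return(invisible(x))
  if (anyDuplicated(x$id))
    stop("duplicate record id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (any(!nzchar(x$residues)))
    stop("empty sequence for record(s): ",
         paste(x$id[!nzchar(x$residues)], collapse = ", "))
  allowed <- if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET
  for (k in seq_len(nrow(x))) {
    ch <- unique(strsplit(x$residues[k], "")[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad))
      stop("record '", x$id[k], "': illegal character(s) ",
           paste(bad, collapse = ", "), " for ", alphabet, " alphabet")
  }
  invisible(x)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s record(s)\n", nrow(x),
              attr(x, "alphabet") %||% "protein"))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    for (k in seq_len(nrow(show)))
      cat(sprintf("  %-20s %5d %s\n", show$id[k], nchar(show$residues[k]),
                  substr(show$residues[k], 1, 40)))
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_lengths <- function(x) setNames(nchar(x$residues), x$id)
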