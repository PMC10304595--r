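#' Percent-identity matrix
#'
#' Symmetric matrix of pairwise percent identities with 100 on the diagonal.
#' `mode = "pairwise"` computes each cell from its own global alignment;
#' `mode = "msa"` computes all cells from one progressive MSA (or a supplied
#' one). Identity uses both-non-gap columns as denominator (see
#' [percent_identity()]).
#'
#' @param recs protein `seq_set` (>= 2 records) — ignored if `msa` is given
#'   with `mode = "msa"`.
#' @param mode `"pairwise"` or `"msa"`.
#' @param params an [alignment_params()].
#' @param msa optional precomputed `msa_result` for `mode = "msa"`.
#' @param denominator passed to [percent_identity()].
#' @return matrix of class `identity_matrix`.
#' @export
identity_matrix <- function(recs, mode = c("pairwise", "msa"),
                            params = alignment_params(), msa = NULL,
                            denominator = "both_ungapped") {
  mode <- match.arg(mode)
  if (mode == "msa") {
    if (is.null(msa)) msa <- progressive_msa(recs, params)
    ids <- names(msa$rows)
    n <- length(ids)
    M <- matrix(100, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- percent_identity(c(msa$rows[i], msa$rows[j]), denominator)
      M[i, j] <- M[j, i] <- v
    }
  } else {
    if (nrow(recs) < 2L) stop("need at least 2 records")
    ids <- recs$id
    n <- length(ids)
    M <- matrix(100, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      pa <- global_align(recs[i, ], recs[j, ], params)
      v <- percent_identity(pa, denominator)
      M[i, j] <- M[j, i] <- v
    }
  }
  class(M) <- c("identity_matrix", class(M))
  M
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d x %d (%%)\n", nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Identity-to-distance conversion
#'
#' `d = 1 - identity/100` (p-distance on identity); optionally
#' Poisson-corrected `-ln(1 - d)` to account for multiple hits.
#' @param idm an `identity_matrix`.
#' @param correction `"none"` or `"poisson"`.
#' @return a `dist_matrix` (symmetric, zero diagonal).
#' @export
identity_to_dist <- function(idm, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  d <- 1 - unclass(idm) / 100
  if (correction == "poisson") d <- -log(pmax(1 - d, 1e-10))
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Bin identity values by the reporting legend
#'
#' Identity reports conventionally highlight bands: under 30, 30-40, 50-60
#' and over 60 percent; the 40-50 band is left unhighlighted.
#' @param values numeric identities (percent).
#' @return factor with levels `<30`, `30-40`, `40-50 (unhighlighted)`,
#'   `50-60`, `>=60`.
#' @export
bin_identity <- function(values) {
  cut(values, breaks = c(-Inf, 30, 40, 50, 60, Inf), right = FALSE,
      labels = c("<30", "30-40", "40-50 (unhighlighted)", "50-60", ">=60"))
}

#' Write an identity matrix as TSV or PHYLIP-style square matrix
#' @param idm an `identity_matrix` (or `dist_matrix`).
#' @param path output path.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_identity <- function(idm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  M <- unclass(idm)
  if (format == "tsv") {
    df <- data.frame(id = rownames(M), M, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(M)), con)
    for (i in seq_len(nrow(M)))
      writeLines(paste0(sprintf("%-10s", rownames(M)[i]),
                        paste(sprintf("%10.5f", M[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP-style square distance (or identity) matrix
#' @param path input path.
#' @return matrix with label dimnames.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  M <- matrix(0, n, n)
  labs <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    labs[i] <- tok[1]
    M[i, ] <- as.numeric(tok[-1])
  }
  dimnames(M) <- list(labs, labs)
  M
}
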