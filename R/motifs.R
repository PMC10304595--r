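#' Diagnostic degenerate motifs of the p25alpha family
#'
#' Three short degenerate motifs discriminate among TPPP-like architectures:
#' \describe{
#'   \item{rossmann}{`G-x-G-x-G-x-x-G-R`, the Rossmann-like block found in the
#'     C-terminal conserved region of long-type TPPPs.}
#'   \item{start_anchor}{`[LV]-x-x-x-[FY]-x-x-F`, sitting at the very start of
#'     the p25alpha domain in long- and short-type TPPPs.}
#'   \item{ggp}{`G-G-P`, in the C-terminal half of short-type proteins.}
#' }
#' A motif is an ordered list of residue sets; `"any"` matches every residue
#' (including `X`); a concrete set also matches `X` is FALSE — `X` only
#' matches `"any"` positions.
#'
#' @param motif_id one of `"rossmann"`, `"start_anchor"`, `"ggp"`.
#' @return a `motif_def`: list with `motif_id`, `pattern` (list of character
#'   vectors or `"any"`) and `placement`.
#' @export
motif_def <- function(motif_id = c("rossmann", "start_anchor", "ggp")) {
  motif_id <- match.arg(motif_id)
  pat <- switch(motif_id,
    rossmann = list("G", "any", "G", "any", "G", "any", "any", "G", "R"),
    start_anchor = list(c("L", "V"), "any", "any", "any", c("F", "Y"),
                        "any", "any", "F"),
    ggp = list("G", "G", "P"))
  placement <- switch(motif_id,
    rossmann = "c_terminal_third_of_domain",
    start_anchor = "domain_start_window",
    ggp = "c_terminal_half_of_domain")
  structure(list(motif_id = motif_id, pattern = pat, placement = placement),
            class = "motif_def")
}

#' All three packaged motif definitions
#' @export
default_motifs <- function() {
  lapply(c("rossmann", "start_anchor", "ggp"), motif_def)
}

match_pattern_at <- function(chars, pattern, offset) {
  # offset 0-based; chars a character vector
  for (p in seq_along(pattern)) {
    want <- pattern[[p]]
    ch <- chars[offset + p]
    if (identical(want, "any")) next
    if (!(ch %in% want)) return(FALSE)
  }
  TRUE
}

#' Find degenerate motif occurrences
#'
#' Scans one protein for each motif, restricted to the motif's placement
#' window. Placements referring to a domain (`domain_start_window`: the first
#' `start_window` residues of the domain span; `c_terminal_half/third`:
#' computed on the domain span) require `domain`; `placement = "anywhere"`
#' scans the whole protein. A hit must fit entirely inside the window.
#'
#' @param rec a single-row protein `seq_set` (or a list with `id`,`residues`).
#' @param motifs list of [motif_def()] objects (default all three).
#' @param domain optional single domain hit (one row of a `domain_hits` table,
#'   or a list with 0-based `start`, `end`).
#' @param placement override the placement of every motif (e.g. `"anywhere"`).
#' @param start_window width of the domain-start window (residues).
#' @return data frame of class `motif_hits`: `protein_id`, `motif_id`,
#'   `start` (0-based), `matched`; rows sorted by motif then offset.
#' @export
find_motifs <- function(rec, motifs = default_motifs(), domain = NULL,
                        placement = NULL, start_window = 15L) {
  id <- rec$id[1]
  chars <- strsplit(rec$residues[1], "")[[1]]
  n <- length(chars)
  rows <- list()
  for (m in motifs) {
    plc <- placement %||% m$placement
    w <- nchar_pattern(m$pattern)
    if (plc == "anywhere") {
      win <- c(0L, n)
    } else {
      if (is.null(domain))
        stop("motif '", m$motif_id, "' placement '", plc,
             "' requires a domain hit")
      ds <- domain$start[1]; de <- domain$end[1]
      dl <- de - ds
      win <- switch(plc,
        domain_start_window = c(ds, min(de, ds + start_window)),
        c_terminal_half_of_domain = c(ds + floor(dl / 2), de),
        c_terminal_third_of_domain = c(ds + ceiling(2 * dl / 3), de),
        stop("unknown placement: ", plc))
    }
    lo <- win[1]; hi <- win[2] - w   # last admissible 0-based offset
    if (hi >= lo && n >= w) {
      for (off in lo:min(hi, n - w)) {
        if (match_pattern_at(chars, m$pattern, off)) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = id, motif_id = m$motif_id, start = off,
            matched = paste(chars[(off + 1):(off + w)], collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), motif_id = character(),
               start = integer(), matched = character())
  class(res) <- c("motif_hits", "data.frame")
  res
}

nchar_pattern <- function(pattern) length(pattern)
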