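#' Length thresholds for TPPP typing
#'
#' Long-, short- and truncated-type TPPPs differ in the length of their
#' p25alpha domain (about 160, 140 and 120 residues respectively); the cuts
#' here are midpoints between those canonical lengths and act on the
#' profile-defined domain span, not the whole protein (divergent short-type
#' proteins of ~121-124 residues would otherwise be miscalled).
#'
#' @param truncated_max longest domain still called truncated (default 127).
#' @param short_min,short_max short-type domain span bounds (128, 152).
#' @param long_min shortest long-type domain (153).
#' @param nterm_extension_min residues before the first domain hit needed to
#'   flag a long N-terminal extension (default 80).
#' @return list of class `type_thresholds`.
#' @export
type_thresholds <- function(truncated_max = 127L, short_min = 128L,
                            short_max = 152L, long_min = 153L,
                            nterm_extension_min = 80L) {
  stopifnot(truncated_max < short_min, short_min <= short_max,
            short_max < long_min)
  structure(list(truncated_max = truncated_max, short_min = short_min,
                 short_max = short_max, long_min = long_min,
                 nterm_extension_min = nterm_extension_min),
            class = "type_thresholds")
}

TYPE_LABELS <- c("long_tppp", "short_tppp", "truncated_tppp", "apicortin",
                 "multidomain_p25", "p25_unclassified", "none")

# merge p25_full / p25_partial hits on the same region: higher score wins,
# exact ties go to p25_full
merge_p25_hits <- function(p25_hits) {
  if (nrow(p25_hits) <= 1L) return(p25_hits)
  h <- p25_hits[order(-p25_hits$score,
                      match(p25_hits$profile_id, c("p25_full", "p25_partial"))), ,
                drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j == i || !keep[j]) next
      if (h$start[j] < h$end[i] && h$start[i] < h$end[j]) keep[j] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

#' Classify one protein from its domain and motif annotation
#'
#' Applies the family typology in a fixed decision order:
#' \enumerate{
#'   \item any DCX hit together with at least one p25alpha hit (full or
#'     partial) is an \strong{apicortin};
#'   \item no DCX but two or more p25alpha hits: \strong{multidomain_p25};
#'   \item a single p25alpha hit: a Rossmann-like motif inside its C-terminal
#'     third makes it \strong{long_tppp}; otherwise the domain-span length
#'     decides \strong{truncated_tppp} (<= `truncated_max`) or
#'     \strong{short_tppp} (<= `short_max`); a long span without the Rossmann
#'     block stays \strong{p25_unclassified};
#'   \item DCX only: \strong{p25_unclassified} with note `DCX-only`;
#'   \item neither: \strong{none}.
#' }
#' Motifs found are recorded as evidence regardless of the label, and
#' `nterm_extended` flags at least `nterm_extension_min` residues before the
#' first domain hit.
#'
#' @param rec single-row protein `seq_set`.
#' @param p25_hits,dcx_hits `domain_hits` rows for this protein.
#' @param motif_hits optional precomputed `motif_hits`; if `NULL` the three
#'   packaged motifs are searched relative to the first merged p25 hit
#'   (or `anywhere` when no domain exists).
#' @param thresholds a [type_thresholds()].
#' @return list of class `type_call`: `protein_id`, `label`, `n_p25`,
#'   `has_dcx`, `domain_lengths`, `motifs_present`, `nterm_extended`, `notes`.
#' @export
classify_protein <- function(rec, p25_hits, dcx_hits,
                             motif_hits = NULL,
                             thresholds = type_thresholds()) {
  p25_hits <- p25_hits[p25_hits$protein_id == rec$id[1], , drop = FALSE]
  dcx_hits <- dcx_hits[dcx_hits$protein_id == rec$id[1], , drop = FALSE]
  if (nrow(p25_hits) && nrow(dcx_hits)) {
    for (i in seq_len(nrow(p25_hits)))
      for (j in seq_len(nrow(dcx_hits)))
        if (p25_hits$start[i] < dcx_hits$end[j] &&
            dcx_hits$start[j] < p25_hits$end[i])
          stop("inconsistent annotation: overlapping p25alpha and DCX hits ",
               "for '", rec$id[1], "'")
  }
  p25 <- merge_p25_hits(p25_hits)
  n_p25 <- nrow(p25)
  has_dcx <- nrow(dcx_hits) > 0L
  dlen <- if (n_p25) as.integer(p25$end - p25$start) else integer(0)

  first_dom <- if (n_p25) p25[1, , drop = FALSE] else
    if (has_dcx) dcx_hits[1, , drop = FALSE] else NULL
  if (is.null(motif_hits)) {
    motif_hits <- if (!is.null(first_dom) && n_p25)
      find_motifs(rec, domain = p25[which.max(dlen), , drop = FALSE])
    else find_motifs(rec, placement = "anywhere")
  }
  motifs_present <- sort(unique(motif_hits$motif_id[
    motif_hits$protein_id == rec$id[1]]))

  notes <- character(0)
  if (!is.null(first_dom)) {
    nterm <- first_dom$start >= thresholds$nterm_extension_min
  } else nterm <- FALSE

  if (has_dcx && n_p25 >= 1L) {
    label <- "apicortin"
  } else if (!has_dcx && n_p25 >= 2L) {
    label <- "multidomain_p25"
  } else if (!has_dcx && n_p25 == 1L) {
    # Rossmann inside the C-terminal third of the single hit?
    ross <- rossmann_in_cterm_third(rec, p25[1, , drop = FALSE])
    L <- dlen[1]
    if (ross) {
      label <- "long_tppp"
    } else if (L <= thresholds$truncated_max) {
      label <- "truncated_tppp"
    } else if (L <= thresholds$short_max) {
      label <- "short_tppp"
    } else {
      label <- "p25_unclassified"
      notes <- c(notes, "long domain without rossmann motif")
    }
    if (L > thresholds$truncated_max - 7L && L < thresholds$short_min + 7L)
      notes <- c(notes, "borderline truncated/short domain length")
  } else if (has_dcx) {
    label <- "p25_unclassified"
    notes <- c(notes, "DCX-only")
  } else {
    label <- "none"
  }
  structure(list(protein_id = rec$id[1], label = label, n_p25 = n_p25,
                 has_dcx = has_dcx, domain_lengths = dlen,
                 domain_spans = if (n_p25) p25[, c("start", "end")] else NULL,
                 motifs_present = motifs_present, nterm_extended = nterm,
                 notes = paste(notes, collapse = "; ")),
            class = "type_call")
}

rossmann_in_cterm_third <- function(rec, hit) {
  mh <- find_motifs(rec, motifs = list(motif_def("rossmann")), domain = hit)
  nrow(mh) > 0L
}

#' @export
print.type_call <- function(x, ...) {
  cat(sprintf("<type_call> %s: %s (p25 hits: %d%s; domain aa: %s%s)\n",
              x$protein_id, x$label, x$n_p25,
              if (x$has_dcx) " + DCX" else "",
              paste(x$domain_lengths, collapse = ","),
              if (nzchar(x$notes)) paste0("; ", x$notes) else ""))
  invisible(x)
}

#' Classify every record in a set
#'
#' Convenience wrapper: scans with the packaged profiles (unless hits are
#' supplied) and classifies each record.
#'
#' @param recs protein `seq_set`.
#' @param hits optional precomputed `domain_hits` for all records.
#' @param thresholds a [type_thresholds()].
#' @param profiles profiles used when `hits` is `NULL`.
#' @return list of `type_call`, one per record, class `type_calls`.
#' @export
classify_all <- function(recs, hits = NULL, thresholds = type_thresholds(),
                         profiles = default_profiles()) {
  if (is.null(hits)) hits <- scan_all(recs, profiles)
  calls <- lapply(seq_len(nrow(recs)), function(k) {
    rec <- recs[k, , drop = FALSE]
    h <- hits[hits$protein_id == rec$id[1], , drop = FALSE]
    classify_protein(rec,
                     h[h$profile_id %in% c("p25_full", "p25_partial"), , drop = FALSE],
                     h[h$profile_id == "dcx", , drop = FALSE],
                     thresholds = thresholds)
  })
  class(calls) <- "type_calls"
  calls
}

#' Tabulate classification labels
#' @param calls a `type_calls` list (or list of `type_call`).
#' @return named integer vector of per-label counts (labels with zero count
#'   omitted); sums to `length(calls)`.
#' @export
summarize_calls <- function(calls) {
  if (!length(calls)) return(integer(0))
  labs <- vapply(calls, `[[`, "", "label")
  tab <- table(factor(labs, levels = TYPE_LABELS))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
}

#' Write a classification report (TSV and/or JSON)
#' @param calls `type_calls`.
#' @param tsv,json output paths (either may be `NULL`).
#' @export
write_calls <- function(calls, tsv = NULL, json = NULL) {
  df <- do.call(rbind, lapply(calls, function(x) data.frame(
    protein_id = x$protein_id, label = x$label, n_p25 = x$n_p25,
    has_dcx = x$has_dcx,
    domain_spans = if (!is.null(x$domain_spans))
      paste(sprintf("%d-%d", x$domain_spans$start + 1L, x$domain_spans$end),
            collapse = ",") else "",
    domain_lengths = paste(x$domain_lengths, collapse = ","),
    motifs_present = paste(x$motifs_present, collapse = ","),
    nterm_extended = x$nterm_extended, notes = x$notes,
    stringsAsFactors = FALSE)))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
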