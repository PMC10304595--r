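profile_cache <- new.env(parent = emptyenv())

#' Build a position-specific scoring profile from a seed alignment
#'
#' Columns of the seed alignment with more than 50% gaps are dropped; the
#' remaining match columns get per-residue log-odds scores
#' `log(((count + pc * bg) / (N + pc)) / bg)` with Laplace pseudocount
#' `pc = 1` and uniform background `bg = 1/20`. `X` scores 0 in every column.
#'
#' The reporting threshold is calibrated empirically: the best local-alignment
#' score of the profile against each of `n_cal` random background sequences of
#' length `cal_len` is computed under a fixed internal seed, and the threshold
#' is the 99.9th percentile of those scores. This makes false positives on
#' background sequence rare (about 1 in 1000) by construction.
#'
#' @param seed_aln character vector of aligned sequences (equal length,
#'   gaps as `-`), at least 4.
#' @param profile_id label, e.g. `"p25_full"`, `"p25_partial"`, `"dcx"`.
#' @param pseudocount Laplace pseudocount.
#' @param calibrate logical; compute the empirical threshold (else 0).
#' @param n_cal,cal_len calibration sample size and sequence length.
#' @param cal_seed internal RNG seed for calibration draws.
#' @return a `pssm_profile`: list with `profile_id`, `length`, `scores`
#'   (length x 21 matrix, columns the 20 residues plus `X`) and `threshold`.
#' @export
build_profile <- function(seed_aln, profile_id, pseudocount = 1,
                          calibrate = TRUE, n_cal = 1000L, cal_len = 500L,
                          cal_seed = 20230608L) {
  if (length(seed_aln) < 4L) stop("need at least 4 seed sequences")
  if (length(unique(nchar(seed_aln))) != 1L)
    stop("seed sequences must be aligned (equal length)")
  rows <- do.call(rbind, strsplit(toupper(seed_aln), ""))
  gapfrac <- colMeans(rows == "-")
  rows <- rows[, gapfrac <= 0.5, drop = FALSE]
  L <- ncol(rows)
  if (L < 30L) stop("profile too short after gap-column removal (", L, " < 30)")
  bg <- 1 / 20
  n <- nrow(rows)
  scores <- matrix(0, L, 21L, dimnames = list(NULL, c(AA20, "X")))
  for (j in seq_len(L)) {
    cnt <- table(factor(rows[, j], levels = AA20))
    nn <- sum(cnt)  # residues only; gaps and X in seeds carry no count
    scores[j, AA20] <- log(((as.numeric(cnt) + pseudocount * bg) /
                              (nn + pseudocount)) / bg)
  }
  prof <- structure(list(profile_id = profile_id, length = L, scores = scores,
                         threshold = 0), class = "pssm_profile")
  if (calibrate)
    prof$threshold <- calibrate_threshold(prof, n_cal, cal_len, cal_seed)
  prof
}

calibrate_threshold <- function(profile, n_cal, cal_len, cal_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cal_seed)
  seqs <- matrix(sample.int(20L, n_cal * cal_len, replace = TRUE),
                 nrow = n_cal, byrow = TRUE)
  best <- cpp_calibrate_scores(profile$scores, seqs, 11, 1)
  as.numeric(quantile(best, 0.999, names = FALSE))
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d match columns, threshold %.2f\n",
              x$profile_id, x$length, x$threshold))
  invisible(x)
}

#' Packaged profiles for the p25alpha family
#'
#' Builds (and memoises) the three profiles used throughout the pipeline from
#' the synthetic seed alignments shipped under `inst/extdata/seeds/`:
#' the full ~160-column p25alpha domain, the shorter partial p25alpha core
#' characteristic of apicortins, and the DCX (doublecortin) domain.
#'
#' @return named list of [build_profile()] results
#'   (`p25_full`, `p25_partial`, `dcx`).
#' @export
default_profiles <- function() {
  if (!is.null(profile_cache$profiles)) return(profile_cache$profiles)
  ids <- c(p25_full = "synthetic_p25_full.fasta",
           p25_partial = "synthetic_p25_partial.fasta",
           dcx = "synthetic_dcx.fasta")
  profs <- lapply(names(ids), function(pid) {
    path <- system.file("extdata", "seeds", ids[[pid]], package = "tpppscan")
    seeds <- read_fasta(path, "protein")
    build_profile(seeds$residues, pid)
  })
  names(profs) <- names(ids)
  profile_cache$profiles <- profs
  profs
}

profile_score_matrix <- function(profile, residues) {
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, colnames(profile$scores))
  if (anyNA(idx)) stop("sequence contains letters outside the profile alphabet")
  profile$scores[, idx, drop = FALSE]
}

#' Scan a protein with a scoring profile
#'
#' Finds the best-scoring local (profile vs. sequence) affine-gap alignments,
#' greedily and non-overlapping: the top segment is reported, its span masked,
#' and the scan repeated until no segment reaches the threshold. Gap penalties
#' are BLAST-scale (open 11, extend 1), which makes long gap runs
#' score-prohibitive.
#'
#' @param rec single-row protein `seq_set`.
#' @param profile a `pssm_profile`.
#' @param threshold minimum reported score (default: the profile's calibrated
#'   threshold). Lowering it never removes a hit, it can only add hits.
#' @param gap_open,gap_extend affine gap penalties.
#' @param max_hits safety cap on reported segments.
#' @return data frame of class `domain_hits` with `protein_id`, `profile_id`,
#'   `start`, `end` (0-based half-open), `score`, `coverage`; sorted by start.
#' @export
scan_profile <- function(rec, profile, threshold = profile$threshold,
                         gap_open = 11, gap_extend = 1, max_hits = 8L) {
  S <- profile_score_matrix(profile, rec$residues[1])
  rows <- list()
  for (k in seq_len(max_hits)) {
    hit <- cpp_affine_local(S, gap_open, gap_extend)
    if (hit$score < threshold || is.na(hit$j0)) break
    rows[[k]] <- data.frame(
      protein_id = rec$id[1], profile_id = profile$profile_id,
      start = hit$j0 - 1L, end = hit$j1, score = hit$score,
      coverage = (hit$i1 - hit$i0 + 1L) / profile$length,
      stringsAsFactors = FALSE)
    S[, hit$j0:hit$j1] <- -1e6
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty_domain_hits()
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("domain_hits", "data.frame")
  res
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), profile_id = character(),
             start = integer(), end = integer(), score = numeric(),
             coverage = numeric())
}

#' Scan a whole record set with all packaged profiles
#'
#' @param recs protein `seq_set`.
#' @param profiles list of profiles (default [default_profiles()]).
#' @param ... passed to [scan_profile()].
#' @return a `domain_hits` data frame over all records and profiles.
#' @export
scan_all <- function(recs, profiles = default_profiles(), ...) {
  out <- list()
  for (k in seq_len(nrow(recs))) {
    rec <- recs[k, , drop = FALSE]
    for (p in profiles) out[[length(out) + 1L]] <- scan_profile(rec, p, ...)
  }
  res <- if (length(out)) do.call(rbind, out) else empty_domain_hits()
  rownames(res) <- NULL
  class(res) <- c("domain_hits", "data.frame")
  res
}

#' Serialize / restore a profile as JSON
#'
#' The layout is a plain object: `profile_id`, `threshold`, `alphabet`, and
#' `scores` as a columns x residues table.
#' @param profile a `pssm_profile`.
#' @param path output (input) path.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(profile_id = profile$profile_id, length = profile$length,
              threshold = profile$threshold,
              alphabet = colnames(profile$scores),
              scores = unname(apply(profile$scores, 1, as.numeric,
                                    simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- if (is.matrix(obj$scores)) obj$scores else
    do.call(rbind, lapply(obj$scores, as.numeric))
  colnames(scores) <- obj$alphabet
  structure(list(profile_id = obj$profile_id, length = obj$length,
                 scores = scores, threshold = obj$threshold),
            class = "pssm_profile")
}

#' Write domain hits as TSV (1-based inclusive coordinates)
#' @param hits a `domain_hits` data frame.
#' @param path output path.
#' @export
write_domain_hits <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L   # 1-based inclusive for reports
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
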