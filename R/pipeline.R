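#' Pipeline run configuration
#'
#' Bundles every setting of a full scan -> classify -> identity -> tree run.
#' A config (plus the input files) fully determines all outputs: re-running
#' an archived config reproduces them byte for byte.
#'
#' @param input path to a FASTA file.
#' @param output_dir directory for all reports (created if needed).
#' @param alphabet `"protein"`, or `"nucleotide"` to six-frame translate
#'   contigs first.
#' @param min_orf_len minimum translated ORF length (nucleotide input).
#' @param thresholds a [type_thresholds()].
#' @param params an [alignment_params()].
#' @param identity_mode `"pairwise"` or `"msa"`.
#' @param trim trim residues N-terminal to the first p25alpha hit before the
#'   identity/tree stage.
#' @param bootstrap_reps bootstrap replicates for tree support (0 = none).
#' @param seed global seed for all stochastic steps.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, output_dir, alphabet = "protein",
                       min_orf_len = 30L, thresholds = type_thresholds(),
                       params = alignment_params(),
                       identity_mode = "pairwise", trim = FALSE,
                       bootstrap_reps = 0L, seed = 1L) {
  structure(list(input = input, output_dir = output_dir, alphabet = alphabet,
                 min_orf_len = as.integer(min_orf_len),
                 thresholds = thresholds, params = params,
                 identity_mode = identity_mode, trim = isTRUE(trim),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_as_list <- function(config) {
  list(input = basename(config$input), alphabet = config$alphabet,
       min_orf_len = config$min_orf_len,
       thresholds = unclass(config$thresholds),
       params = unclass(config$params),
       identity_mode = config$identity_mode, trim = config$trim,
       bootstrap_reps = config$bootstrap_reps, seed = config$seed)
}

#' Run the full annotation pipeline
#'
#' Reads sequences (translating nucleotide contigs in six frames when asked),
#' scans them with the packaged p25alpha-full, p25alpha-partial and DCX
#' profiles, classifies every record, and — for records with at least one
#' p25alpha hit — computes the percent-identity matrix, a progressive MSA,
#' and a neighbor-joining tree (with bootstrap supports when
#' `bootstrap_reps > 0`). Records whose domain hit touches a sequence
#' terminus with profile coverage < 0.8 are flagged as possibly incomplete.
#'
#' Outputs written to `output_dir`: `classification.tsv` / `.json`,
#' `domain_hits.tsv`, `identity.tsv`, `identity_bins.tsv`, `msa.fasta`,
#' `tree.nwk`, `dropped.tsv`, `manifest.json` and `run.log`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisible list: `status` (0 ok, 2 no hits), `calls`, `hits`,
#'   `identity`, `msa`, `tree`, paths of the written reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  loglines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    loglines <<- c(loglines, msg)
    if (!quiet) message(msg)
  }
  set.seed(config$seed)
  recs <- read_fasta(config$input, config$alphabet)
  if (config$alphabet == "nucleotide") {
    say("translating %d contig(s) in six frames", nrow(recs))
    recs <- six_frame_translate(recs, config$min_orf_len)
    say("%d candidate ORFs of >= %d aa", nrow(recs), config$min_orf_len)
  }
  profiles <- default_profiles()
  hits <- scan_all(recs, profiles)
  calls <- classify_all(recs, hits, config$thresholds, profiles)
  # incomplete-sequence warnings: hit touching a terminus with low coverage
  for (k in seq_len(nrow(hits))) {
    len <- nchar(recs$residues[recs$id == hits$protein_id[k]])
    if (hits$coverage[k] < 0.8 && (hits$start[k] == 0L || hits$end[k] == len))
      say("warning: %s %s hit touches a terminus with coverage %.2f (incomplete sequence?)",
          hits$protein_id[k], hits$profile_id[k], hits$coverage[k])
  }
  write_domain_hits(hits, file.path(config$output_dir, "domain_hits.tsv"))
  write_calls(calls, tsv = file.path(config$output_dir, "classification.tsv"),
              json = file.path(config$output_dir, "classification.json"))
  labs <- vapply(calls, `[[`, "", "label")
  keep <- vapply(calls, function(x) x$n_p25 >= 1L, TRUE)
  dropped <- data.frame(protein_id = recs$id[!keep],
                        reason = ifelse(labs[!keep] == "none",
                                        "no p25alpha/DCX hit",
                                        "no p25alpha hit"))
  write.table(dropped, file.path(config$output_dir, "dropped.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  status <- 0L
  idm <- NULL; msa <- NULL; tree <- NULL
  if (!any(keep)) {
    say("no p25alpha/DCX hits; emitting empty reports")
    status <- 2L
    file.create(file.path(config$output_dir,
                          c("identity.tsv", "msa.fasta", "tree.nwk")))
  } else {
    sel <- recs[keep, , drop = FALSE]
    if (config$trim) {
      sel <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
        h <- hits[hits$protein_id == sel$id[i] &
                    hits$profile_id %in% c("p25_full", "p25_partial"), ,
                  drop = FALSE]
        tr <- trim_to_domain(sel[i, , drop = FALSE], h[which.min(h$start), , drop = FALSE])
        tr$id <- sub("::trimmed$", "", tr$id)
        tr
      }))
      class(sel) <- c("seq_set", "data.frame")
    }
    if (nrow(sel) >= 2L) {
      msa <- progressive_msa(sel, config$params)
      idm <- identity_matrix(sel, mode = config$identity_mode,
                             params = config$params, msa = msa)
      write_identity(idm, file.path(config$output_dir, "identity.tsv"))
      ut <- upper.tri(idm)
      bins <- data.frame(
        a = rownames(idm)[row(idm)[ut]], b = colnames(idm)[col(idm)[ut]],
        identity = idm[ut], bin = as.character(bin_identity(idm[ut])))
      write.table(bins, file.path(config$output_dir, "identity_bins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_msa(msa, file.path(config$output_dir, "msa.fasta"))
      if (nrow(sel) >= 3L) {
        if (config$bootstrap_reps > 0L) {
          tree <- bootstrap_support(msa, config$bootstrap_reps,
                                    seed = config$seed)
        } else {
          tree <- neighbor_joining(identity_to_dist(idm))
        }
        write_newick(tree, file.path(config$output_dir, "tree.nwk"))
      } else say("fewer than 3 sequences with hits; no tree built")
    } else say("fewer than 2 sequences with hits; no identity matrix built")
  }
  cfg <- config_as_list(config)
  tmp <- tempfile()
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(tool = "tpppscan",
                   version = as.character(utils::packageVersion("tpppscan")),
                   config = cfg,
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = config$seed, status = status,
                   n_records = nrow(recs),
                   label_counts = as.list(summarize_calls(calls)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(loglines, logf)
  invisible(list(status = status, records = recs, hits = hits, calls = calls,
                 identity = idm, msa = msa, tree = tree,
                 output_dir = config$output_dir))
}
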