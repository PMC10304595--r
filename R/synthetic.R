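core_cache <- new.env(parent = emptyenv())

synthetic_cores <- function() {
  if (!is.null(core_cache$cores)) return(core_cache$cores)
  path <- system.file("extdata", "synthetic_cores.fasta", package = "tpppscan")
  fa <- read_fasta(path, "protein")
  core_cache$cores <- setNames(fa$residues, fa$id)
  core_cache$cores
}

# motif layout of the packaged master p25alpha core (0-based offsets)
CORE_MOTIFS <- list(
  start_anchor = c(start = 2L, len = 8L),
  ggp = c(start = 95L, len = 3L),
  rossmann = c(start = 145L, len = 9L))
PARTIAL_OFFSET <- 30L  # partial core = master[31..130] (1-based)

SIM_ARCHITECTURES <- c("long_tppp", "short_tppp", "truncated_tppp",
                       "apicortin", "multidomain_p25")

#' Simulation specification for a synthetic protein family
#'
#' Defines the conditions a simulated family is generated under. Defaults
#' mirror the divergence regime the pipeline is meant to handle: moderate
#' point substitution (0.1 expected substitutions per site per unit branch
#' length), rare indels (0.005 per site, geometric lengths with mean 2) and
#' modest terminal flanks. Identical specs give bit-identical output.
#'
#' @param architecture one of `long_tppp`, `short_tppp`, `truncated_tppp`,
#'   `apicortin`, `multidomain_p25`.
#' @param n_taxa number of leaves (>= 2).
#' @param tree an `ape::phylo` with `n_taxa` tips, or `"random_yule"` for a
#'   pure-birth tree rescaled to unit height.
#' @param subst_rate expected substitutions per site per unit branch length.
#' @param indel_rate expected indel events per site per unit branch length.
#' @param nterm_len,cterm_len flank lengths around the domain architecture.
#' @param protect_motifs keep the diagnostic motif sites untouched so the
#'   designed label stays well-defined; turn off to simulate motif decay
#'   (divergent, piroplasmid-like families).
#' @param seed integer seed; the topology and template are drawn under
#'   `seed`, per-branch mutations under `seed + 1` (the package's
#'   stream-splitting rule).
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(architecture, n_taxa = 8L, tree = "random_yule",
                     subst_rate = 0.1, indel_rate = 0.005,
                     nterm_len = 15L, cterm_len = 10L,
                     protect_motifs = TRUE, seed = 1L) {
  architecture <- match.arg(architecture, SIM_ARCHITECTURES)
  stopifnot(n_taxa >= 2L, subst_rate >= 0, indel_rate >= 0,
            nterm_len >= 0L, cterm_len >= 0L)
  structure(list(architecture = architecture, n_taxa = as.integer(n_taxa),
                 tree = tree, subst_rate = subst_rate,
                 indel_rate = indel_rate, nterm_len = as.integer(nterm_len),
                 cterm_len = as.integer(cterm_len),
                 protect_motifs = isTRUE(protect_motifs),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

rand_residues <- function(n) if (n) sample(AA20, n, replace = TRUE) else character(0)

#' Build an unmutated template of a given architecture
#'
#' Assembles a template protein from the packaged consensus cores:
#' long = 160-aa p25alpha core (Rossmann block in its C-terminal third);
#' short = the first 140 core residues (start anchor near the domain start,
#' GGP in the C-terminal half, no Rossmann); truncated = the first 120
#' residues (C-terminal third missing); apicortin = partial p25alpha core +
#' linker + DCX core (optionally with a long disordered-style N-terminal
#' flank); multidomain = two short cores separated by a linker. Flanks and
#' linkers are random background residues drawn under `seed`.
#'
#' @param architecture see [sim_spec()].
#' @param nterm_len,cterm_len flank lengths.
#' @param linker_len linker length between domains.
#' @param seed RNG seed for the random flanks/linkers.
#' @param id record id.
#' @return list: `record` (single-row protein `seq_set`) and `truth`
#'   (designed label, domain table, motif table; 0-based half-open spans).
#' @export
make_template <- function(architecture, nterm_len = 15L, cterm_len = 10L,
                          linker_len = 25L, seed = 1L, id = "template") {
  architecture <- match.arg(architecture, SIM_ARCHITECTURES)
  cores <- synthetic_cores()
  set.seed(seed)
  nterm <- rand_residues(nterm_len)
  cterm <- rand_residues(cterm_len)
  master <- strsplit(cores[["p25_core"]], "")[[1]]
  partial <- strsplit(cores[["p25_partial_core"]], "")[[1]]
  dcx <- strsplit(cores[["dcx_core"]], "")[[1]]

  motif_rows <- function(base, which_motifs, limit) {
    do.call(rbind, lapply(which_motifs, function(m) {
      mm <- CORE_MOTIFS[[m]]
      if (mm["start"] + mm["len"] > limit) return(NULL)
      data.frame(motif_id = m, start = base + mm[["start"]],
                 len = mm[["len"]], stringsAsFactors = FALSE)
    }))
  }
  b <- nterm_len
  if (architecture == "long_tppp") {
    chars <- c(nterm, master, cterm)
    doms <- data.frame(profile_id = "p25_full", start = b, end = b + 160L)
    mots <- motif_rows(b, c("start_anchor", "ggp", "rossmann"), 160L)
  } else if (architecture == "short_tppp") {
    chars <- c(nterm, master[1:140], cterm)
    doms <- data.frame(profile_id = "p25_full", start = b, end = b + 140L)
    mots <- motif_rows(b, c("start_anchor", "ggp"), 140L)
  } else if (architecture == "truncated_tppp") {
    chars <- c(nterm, master[1:120], cterm)
    doms <- data.frame(profile_id = "p25_full", start = b, end = b + 120L)
    mots <- motif_rows(b, c("start_anchor", "ggp"), 120L)
  } else if (architecture == "apicortin") {
    linker <- rand_residues(linker_len)
    chars <- c(nterm, partial, linker, dcx, cterm)
    doms <- data.frame(
      profile_id = c("p25_partial", "dcx"),
      start = c(b, b + length(partial) + linker_len),
      end = c(b + length(partial),
              b + length(partial) + linker_len + length(dcx)))
    # ggp sits inside the partial core, shifted by the core offset
    mots <- data.frame(motif_id = "ggp",
                       start = b + CORE_MOTIFS$ggp[["start"]] - PARTIAL_OFFSET,
                       len = 3L)
  } else { # multidomain_p25
    linker <- rand_residues(linker_len)
    shortc <- master[1:140]
    chars <- c(nterm, shortc, linker, shortc, cterm)
    b2 <- b + 140L + linker_len
    doms <- data.frame(profile_id = c("p25_full", "p25_full"),
                       start = c(b, b2), end = c(b + 140L, b2 + 140L))
    mots <- rbind(motif_rows(b, c("start_anchor", "ggp"), 140L),
                  motif_rows(b2, c("start_anchor", "ggp"), 140L))
  }
  rec <- protein_set(id, paste(chars, collapse = ""))
  list(record = rec,
       truth = list(label = architecture, domains = doms, motifs = mots))
}

# protected template coordinates (0-based) of the truth motifs
protected_sites <- function(truth) {
  if (is.null(truth$motifs) || !nrow(truth$motifs)) return(integer(0))
  unlist(lapply(seq_len(nrow(truth$motifs)), function(k)
    truth$motifs$start[k] + seq_len(truth$motifs$len[k]) - 1L))
}

# one branch of evolution; state = list(chars, origin) where origin maps each
# current position to a template coordinate (0-based) or NA for insertions
evolve_branch <- function(state, t, spec, protected) {
  chars <- state$chars
  origin <- state$origin
  n <- length(chars)
  is_protected <- origin %in% protected
  # substitutions: Poisson(subst_rate * t) events per site, uniform residues
  p_hit <- 1 - exp(-spec$subst_rate * t)
  hit <- runif(n) < p_hit
  if (spec$protect_motifs) hit <- hit & !is_protected
  if (any(hit)) chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  # indels
  n_ind <- rpois(1L, spec$indel_rate * n * t)
  for (e in seq_len(n_ind)) {
    g <- 1L + rgeom(1L, 0.5)
    del <- runif(1) < 0.5
    ok <- FALSE
    for (try in 1:20) {
      if (del) {
        if (length(chars) <= g + 1L) break
        pos <- sample.int(length(chars) - g + 1L, 1L)
        span <- pos:(pos + g - 1L)
        if (spec$protect_motifs && any(origin[span] %in% protected)) next
        chars <- chars[-span]; origin <- origin[-span]
      } else {
        pos <- sample.int(length(chars) + 1L, 1L)  # insert before pos
        if (spec$protect_motifs && pos > 1L && pos <= length(chars)) {
          # do not split a protected motif run
          a <- origin[pos - 1L]; b2 <- origin[pos]
          if (!is.na(a) && !is.na(b2) && a %in% protected && b2 %in% protected) next
        }
        ins <- sample(AA20, g, replace = TRUE)
        chars <- append(chars, ins, after = pos - 1L)
        origin <- append(origin, rep(NA_integer_, g), after = pos - 1L)
      }
      ok <- TRUE
      break
    }
    if (!ok) next
    is_protected <- origin %in% protected
  }
  list(chars = chars, origin = origin)
}

# recompute truth spans for a leaf from its origin map
leaf_truth <- function(state, truth) {
  doms <- truth$domains
  out <- doms
  for (k in seq_len(nrow(doms))) {
    idx <- which(!is.na(state$origin) & state$origin >= doms$start[k] &
                   state$origin < doms$end[k])
    if (!length(idx)) { out$start[k] <- 0L; out$end[k] <- 0L; next }
    out$start[k] <- min(idx) - 1L
    out$end[k] <- max(idx)
  }
  mots <- truth$motifs
  if (!is.null(mots) && nrow(mots)) {
    for (k in seq_len(nrow(mots))) {
      idx <- which(!is.na(state$origin) & state$origin == mots$start[k])
      mots$start[k] <- if (length(idx)) idx[1] - 1L else NA_integer_
    }
  }
  list(label = truth$label, domains = out, motifs = mots)
}

#' Evolve a synthetic family along a tree
#'
#' The architecture template is evolved along every branch of the (given or
#' simulated) tree: per-site Poisson substitutions with uniform replacement
#' residues, and Poisson indel events with geometric lengths (mean 2),
#' optionally avoiding the protected motif mask. Ground-truth domain and
#' motif coordinates are tracked through all indels. A branch whose indels
#' shrink a domain span below 30 residues is redrawn (up to 10 times, with a
#' warning).
#'
#' @param spec a [sim_spec()].
#' @return list of class `sim_family`: `records` (protein `seq_set`, one per
#'   leaf), `truth` (per-record list of label/domain/motif coordinates),
#'   `true_tree` (`phylo`), `spec`.
#' @export
evolve_family <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  if (identical(spec$tree, "random_yule")) {
    tr <- ape::rphylo(spec$n_taxa, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  } else {
    tr <- spec$tree
    stopifnot(inherits(tr, "phylo"), length(tr$tip.label) == spec$n_taxa)
  }
  tr$tip.label <- sprintf("t%02d", seq_len(spec$n_taxa))
  tmpl <- make_template(spec$architecture, seed = spec$seed)
  protected <- protected_sites(tmpl$truth)

  set.seed(spec$seed + 1L)  # mutation stream
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode <- tr$Nnode
  states <- vector("list", ntip + nnode)
  chars0 <- strsplit(tmpl$record$residues, "")[[1]]
  states[[root]] <- list(chars = chars0,
                         origin = seq_along(chars0) - 1L)
  ord <- ape::reorder.phylo(tr, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    t <- ord$edge.length[k]
    for (try in 1:10) {
      st <- evolve_branch(states[[par]], t, spec, protected)
      lt <- leaf_truth(st, tmpl$truth)
      if (all(lt$domains$end - lt$domains$start >= 30L)) break
      warning("indel drift shrank a domain below 30 residues; resampling branch")
    }
    states[[child]] <- st
  }
  ids <- tr$tip.label
  recs <- protein_set(ids, vapply(seq_len(ntip), function(i)
    paste(states[[i]]$chars, collapse = ""), ""))
  truth <- lapply(seq_len(ntip), function(i) leaf_truth(states[[i]], tmpl$truth))
  names(truth) <- ids
  structure(list(records = recs, truth = truth, true_tree = tr, spec = spec,
                 template = tmpl), class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %s, %d taxa, subst %.3g, indel %.3g, seed %d\n",
              x$spec$architecture, x$spec$n_taxa, x$spec$subst_rate,
              x$spec$indel_rate, x$spec$seed))
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits sequences (FASTA), truth labels and spans (TSV, 1-based inclusive),
#' the true tree (Newick) and the spec echo (JSON).
#' @param fam a `sim_family`.
#' @param dir output directory (created if needed).
#' @export
write_sim_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$records, file.path(dir, "family.fasta"))
  rows <- do.call(rbind, lapply(names(fam$truth), function(id) {
    tt <- fam$truth[[id]]
    data.frame(protein_id = id, label = tt$label,
               domains = paste(sprintf("%s:%d-%d", tt$domains$profile_id,
                                       tt$domains$start + 1L, tt$domains$end),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_newick(fam$true_tree, file.path(dir, "true_tree.nwk"))
  sp <- fam$spec
  sp$tree <- if (identical(sp$tree, "random_yule")) "random_yule" else "user_tree"
  jsonlite::write_json(unclass(sp), file.path(dir, "sim_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
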