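#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Determinism is
#' guaranteed: when several pairs minimise Q, the pair whose (lexicographically
#' smallest representative leaf labels) sorts first is joined. Negative branch
#' lengths are clamped to 0 and the deficit moved to the sibling edge, so the
#' path length of the joined pair is preserved. On additive distance matrices
#' the generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and label dimnames
#'   (>= 3 labels), e.g. from [identity_to_dist()].
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  M <- unclass(d)
  if (is.null(dim(M)) || nrow(M) != ncol(M)) stop("need a square matrix")
  labs <- rownames(M)
  if (is.null(labs) || anyDuplicated(labs)) stop("need unique label dimnames")
  n <- nrow(M)
  if (n < 3L) stop("need at least 3 labels")
  if (max(abs(M - t(M))) > 1e-8) stop("asymmetric distance matrix")
  # active nodes: representative label (lexicographic min leaf) + newick
  rep_lab <- labs
  nwk <- labs
  D <- M
  while (length(rep_lab) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9 * (1 + abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0; if (vi < 0) vi <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    rep_lab <- c(rep_lab[keep], new_rep)
    nwk <- c(nwk[keep], new_nwk)
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], v[1], nwk[2], v[2],
                 nwk[3], v[3])
  ape::read.tree(text = txt)
}

identity_rows_matrix <- function(rows, denominator = "both_ungapped") {
  ids <- names(rows)
  n <- length(ids)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- percent_identity(c(rows[i], rows[j]), denominator)
    if (is.na(v)) v <- 0
    M[i, j] <- M[j, i] <- v
  }
  class(M) <- c("identity_matrix", class(M))
  M
}

nj_from_msa_rows <- function(rows, correction = "none") {
  idm <- identity_rows_matrix(rows)
  neighbor_joining(identity_to_dist(idm, correction))
}

#' Bootstrap support for the neighbor-joining tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' identity-distance NJ tree per replicate, and reports for each internal
#' edge of the original tree the fraction of replicates containing the same
#' bipartition. Deterministic given `seed`.
#'
#' @param msa an `msa_result`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @param correction distance correction, see [identity_to_dist()].
#' @param .resample optional hook `function(n_cols, rep)` returning the column
#'   indices of a replicate (used for testing; default: iid resampling).
#' @return the original NJ tree (`phylo`) with supports in \[0,1\] as
#'   `node.label`.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L,
                              correction = "none", .resample = NULL) {
  stopifnot(n_reps >= 1L)
  rows <- msa$rows
  L <- nchar(rows[1])
  chars <- do.call(rbind, strsplit(rows, ""))
  orig <- nj_from_msa_rows(rows, correction)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- if (is.null(.resample)) sample.int(L, L, replace = TRUE)
           else .resample(L, r)
    rrows <- setNames(apply(chars[, idx, drop = FALSE], 1, paste,
                            collapse = ""), names(rows))
    reps[[r]] <- nj_from_msa_rows(rrows, correction)
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(orig, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  orig$node.label <- formatC(cnt / n_reps, format = "g")
  orig
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions; both trees must
#' share the same leaf set.
#' @param t1,t2 `phylo` trees.
#' @return non-negative integer.
#' @export
compare_topologies <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Does a label set form a clade?
#'
#' Roots the tree (on `outgroup`, or at the midpoint when no outgroup is
#' given) and tests whether `group` is monophyletic.
#' @param tree a `phylo`.
#' @param group character vector of tip labels (non-empty proper subset).
#' @param outgroup a tip label outside `group`, or `NULL` for midpoint
#'   rooting.
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, group, outgroup = NULL) {
  tips <- tree$tip.label
  stopifnot(length(group) >= 1L, all(group %in% tips),
            length(group) < length(tips))
  if (!is.null(outgroup)) {
    if (outgroup %in% group) stop("outgroup must lie outside the group")
    rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    rooted <- phangorn::midpoint(tree)
  }
  if (length(group) == 1L) return(TRUE)
  ape::is.monophyletic(rooted, group)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape; bootstrap supports travel as internal node labels.
#' @param tree a `phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
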