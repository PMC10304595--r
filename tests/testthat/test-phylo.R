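additive_matrix <- function(tree) ape::cophenetic.phylo(tree)

test_that("NJ inverts an additive 4-taxon matrix exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- additive_matrix(ref)
  est <- neighbor_joining(D)
  expect_equal(compare_topologies(est, ref), 0L)
  expect_equal(additive_matrix(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-8)
})

test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("equidistant matrices resolve deterministically and reproducibly", {
  D <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
})

test_that("NJ rejects malformed input", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "asymmetric")
})

test_that("NJ recovers random additive trees and agrees with ape's NJ", {
  set.seed(22)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    ref <- ape::unroot(ape::rtree(n))
    ref$edge.length <- runif(nrow(ref$edge), 0.1, 2)
    D <- additive_matrix(ref)
    est <- neighbor_joining(D)
    expect_equal(compare_topologies(est, ref), 0L)
    expect_lt(max(abs(additive_matrix(est)[rownames(D), colnames(D)] - D)),
              1e-6)
    expect_equal(compare_topologies(est, ape::nj(D)), 0L)
  }
})

test_that("RF distance matches a brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(compare_topologies(t1, t1), 0L)
  expect_equal(compare_topologies(t1, t2), 2L)
  expect_error(compare_topologies(t1, ape::rtree(5)), "leaf set")
  set.seed(23)
  for (k in 1:15) {
    a <- ape::rtree(8); b <- ape::rtree(8)
    b$tip.label <- sample(a$tip.label)
    expect_equal(compare_topologies(a, b), brute_rf(a, b))
  }
})

test_that("monophyly checks agree with brute-force clade enumeration", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  expect_true(is_monophyletic(tr, "A", "D"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "E"), "D"))
  expect_true(is_monophyletic(tr, c("A", "B"), "D"))
  expect_false(is_monophyletic(tr, c("A", "C", "D"), "E"))
  expect_error(is_monophyletic(tr, c("A", "D"), "D"), "outside")
  set.seed(24)
  for (k in 1:15) {
    tr <- ape::rtree(8)
    grp <- sample(tr$tip.label, sample(2:5, 1))
    out <- sample(setdiff(tr$tip.label, grp), 1)
    expect_equal(is_monophyletic(tr, grp, out),
                 brute_monophyletic(tr, grp, out),
                 label = paste(k))
  }
})

test_that("Newick round trip preserves topology, lengths and supports", {
  set.seed(25)
  tr <- ape::rtree(9)
  tr$node.label <- formatC(runif(tr$Nnode), format = "g")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(compare_topologies(tr, back), 0L)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-6)
  expect_equal(back$node.label, tr$node.label)
})

test_that("bootstrap with the identity resampling stub gives full support", {
  fam <- evolve_family(sim_spec("short_tppp", n_taxa = 5, subst_rate = 0.3,
                                seed = 26))
  msa <- progressive_msa(fam$records)
  tr <- bootstrap_support(msa, n_reps = 1, seed = 1,
                          .resample = function(n, r) seq_len(n))
  expect_true(all(as.numeric(tr$node.label) == 1))
})

test_that("bootstrap supports are in range and bit-reproducible", {
  set.seed(27)
  recs <- protein_set(paste0("r", 1:4),
                      vapply(1:4, function(i) rand_protein(80), ""))
  msa <- progressive_msa(recs)
  t1 <- bootstrap_support(msa, n_reps = 30, seed = 5)
  s <- as.numeric(t1$node.label)
  expect_true(all(s >= 0 & s <= 1))
  t2 <- bootstrap_support(msa, n_reps = 30, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("true bipartitions of a low-divergence family earn high support", {
  # known balanced 8-taxon tree with resolvable internal edges
  known <- ape::unroot(ape::read.tree(text = paste0(
    "(((t1:0.2,t2:0.2):0.3,(t3:0.2,t4:0.2):0.3):0.3,",
    "((t5:0.2,t6:0.2):0.3,(t7:0.2,t8:0.2):0.3):0.3);")))
  sup <- numeric(0)
  for (s in 1:5) {
    fam <- evolve_family(sim_spec("short_tppp", n_taxa = 8, tree = known,
                                  subst_rate = 0.1, indel_rate = 0,
                                  seed = 400 + s))
    msa <- progressive_msa(fam$records)
    bt <- bootstrap_support(msa, n_reps = 100, seed = s)
    true_bp <- bipartitions(fam$true_tree)
    est_bp <- bipartitions(bt)
    # supports of estimated bipartitions that are also true bipartitions
    pp <- ape::prop.part(bt)
    labels <- attr(pp, "labels")
    n <- length(labels)
    for (i in seq_along(pp)) {
      side <- sort(labels[pp[[i]]])
      if (length(side) <= 1L || length(side) >= n - 1L) next
      other <- sort(setdiff(labels, side))
      canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
        side else other
      if (paste(canon, collapse = ",") %in% true_bp)
        sup <- c(sup, as.numeric(bt$node.label[i]))
    }
  }
  expect_gte(mean(sup), 0.9)
})

test_that("PHYLIP square matrices round-trip through write/read", {
  fam <- evolve_family(sim_spec("short_tppp", n_taxa = 4, subst_rate = 0.2,
                                seed = 28))
  idm <- identity_matrix(fam$records)
  f <- withr::local_tempfile(fileext = ".dist")
  write_identity(idm, f, format = "phylip")
  M <- read_phylip_matrix(f)
  expect_equal(M, unclass(idm), tolerance = 1e-5)
})
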