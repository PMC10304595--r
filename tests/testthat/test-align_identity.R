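test_that("N-terminal trimming keeps everything from the first hit onward", {
  set.seed(3)
  rec <- protein_set("p", rand_protein(200))
  h0 <- data.frame(protein_id = "p", start = 0L, end = 160L)
  t0 <- trim_to_domain(rec, h0)
  expect_equal(t0$residues, rec$residues)
  expect_equal(t0$id, "p::trimmed")

  h80 <- data.frame(protein_id = "p", start = 80L, end = 200L)
  expect_equal(nchar(trim_to_domain(rec, h80)$residues), 120L)
  expect_error(trim_to_domain(rec, data.frame(protein_id = "q", start = 0L)),
               "belong")
})

test_that("re-scanning a trimmed protein puts the domain at position 0", {
  profs <- default_profiles()
  tm <- make_template("long_tppp", seed = 14)
  h <- scan_profile(tm$record, profs$p25_full)
  tr <- trim_to_domain(tm$record, h[1, ])
  h2 <- scan_profile(tr, profs$p25_full)
  expect_equal(h2$start[1], 0L)
})

test_that("global alignment handles identity and single-gap cases", {
  a <- global_align(protein_set("a", "MKVLLY"), protein_set("b", "MKVLLY"))
  expect_false(any(grepl("-", a$aligned)))
  expect_equal(percent_identity(a), 100)

  g <- global_align(protein_set("a", "ACD"), protein_set("b", "AD"))
  expect_equal(g$aligned, c("ACD", "A-D"))
})

test_that("Gotoh scores equal exhaustive enumeration on short sequences", {
  B <- tpppscan:::get_subst_matrix("BLOSUM62")
  set.seed(15)
  ab <- c("A", "C", "D", "E")
  for (k in 1:40) {
    a <- paste(sample(ab, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(ab, sample(1:6, 1), TRUE), collapse = "")
    got <- global_align(protein_set("a", a), protein_set("b", b))$score
    expect_equal(got, brute_align_score(a, b, B), tolerance = 1e-9,
                 label = paste(a, b))
  }
})

test_that("percent identity counts both-ungapped columns, rounded half-up", {
  expect_equal(percent_identity(c("AC-D", "ACED")), 100)
  expect_equal(percent_identity(c("AAA", "AAC")), 66.67)
  expect_equal(percent_identity(c("ACDE", "ACDK")), 75)
  # alternative denominators
  expect_equal(percent_identity(c("AC-D", "ACED"), "alignment_length"), 75)
  expect_equal(percent_identity(c("AC-D", "ACED"), "shorter_seq"), 100)
  # brute-force column count on random gapped rows; symmetry
  set.seed(16)
  for (k in 1:20) {
    n <- 30
    a <- sample(c(AA, "-"), n, TRUE); b <- sample(c(AA, "-"), n, TRUE)
    ra <- paste(a, collapse = ""); rb <- paste(b, collapse = "")
    both <- a != "-" & b != "-"
    if (!sum(both)) next
    want <- floor(100 * 100 * sum(both & a == b) / sum(both) + 0.5) / 100
    expect_equal(percent_identity(c(ra, rb)), want)
    expect_equal(percent_identity(c(ra, rb)), percent_identity(c(rb, ra)))
  }
})

test_that("progressive MSA base cases and row recovery", {
  set.seed(17)
  a <- rand_protein(60); b <- rand_protein(55)
  recs <- protein_set(c("a", "b"), c(a, b))
  msa2 <- progressive_msa(recs)
  pa <- global_align(recs[1, ], recs[2, ])
  expect_equal(unname(msa2$rows), pa$aligned)

  tri <- protein_set(c("x", "y", "z"), rep(a, 3))
  msa3 <- progressive_msa(tri)
  expect_false(any(grepl("-", msa3$rows)))

  expect_error(progressive_msa(protein_set(c("a", "b"), c(a, b))[c(1, 1), ]),
               "duplicate")

  fam <- evolve_family(sim_spec("short_tppp", n_taxa = 6, subst_rate = 0.25,
                                seed = 18))
  msa <- progressive_msa(fam$records)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  expect_equal(unname(gsub("-", "", msa$rows[fam$records$id])),
               fam$records$residues)
})

test_that("planted anchor motifs align into common MSA columns", {
  ok <- 0L
  for (s in 1:10) {
    fam <- evolve_family(sim_spec("short_tppp", n_taxa = 6, subst_rate = 0.1,
                                  indel_rate = 0.01, seed = 100 + s))
    msa <- progressive_msa(fam$records)
    # map each sequence's true anchor start to its MSA column
    cols <- vapply(fam$records$id, function(id) {
      pos <- fam$truth[[id]]$motifs$start[
        fam$truth[[id]]$motifs$motif_id == "start_anchor"]
      row <- msa$rows[[id]]
      ungapped <- cumsum(strsplit(row, "")[[1]] != "-")
      which(ungapped == pos + 1L)[1]
    }, 1)
    if (length(unique(cols)) == 1L) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("identity matrices are symmetric with unit diagonal in both modes", {
  fam <- evolve_family(sim_spec("truncated_tppp", n_taxa = 5,
                                subst_rate = 0.2, seed = 19))
  two <- protein_set(c("u", "v"), rep(fam$records$residues[1], 2))
  expect_equal(unclass(identity_matrix(two))["u", "v"], 100)
  for (mode in c("pairwise", "msa")) {
    m <- unclass(identity_matrix(fam$records, mode = mode))
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(100, 5))
    expect_true(all(m >= 0 & m <= 100))
  }
})

test_that("identity distances are zero on the diagonal and symmetric", {
  fam <- evolve_family(sim_spec("short_tppp", n_taxa = 4, subst_rate = 0.3,
                                seed = 20))
  idm <- identity_matrix(fam$records)
  d <- unclass(identity_to_dist(idm))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  dp <- unclass(identity_to_dist(idm, "poisson"))
  expect_true(all(dp[upper.tri(dp)] >= d[upper.tri(d)]))
})

test_that("identity bins follow the reporting legend", {
  b <- bin_identity(c(25, 30, 39.9, 45, 55, 60, 78))
  expect_equal(as.character(b),
               c("<30", "30-40", "30-40", "40-50 (unhighlighted)",
                 "50-60", ">=60", ">=60"))
})
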