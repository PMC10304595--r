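test_that("profile construction gives sensible log-odds", {
  seeds <- rep(strrep("A", 30), 4)
  p <- build_profile(seeds, "test", calibrate = FALSE)
  expect_equal(p$length, 30L)
  expect_true(all(apply(p$scores[, AA], 1, which.max) == 1L))  # A everywhere
  expect_true(all(p$scores[, "X"] == 0))

  # a column evenly split among all 20 residues scores ~0 for every residue
  seeds20 <- vapply(AA, function(a) paste0(strrep("C", 29), a), "")
  p20 <- build_profile(seeds20, "even", calibrate = FALSE)
  expect_true(all(abs(p20$scores[30, AA]) < 1e-12))

  expect_error(build_profile(rep(strrep("A", 30), 3), "few"), "at least 4")
})

test_that("columns with >50% gaps are dropped", {
  seeds <- c("AAAA-AAAAAAAAAAAAAAAAAAAAAAAAAAA",
             "AAAA-AAAAAAAAAAAAAAAAAAAAAAAAAAA",
             "AAAA-AAAAAAAAAAAAAAAAAAAAAAAAAAA",
             "AAAACAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  p <- build_profile(seeds, "gapcol", calibrate = FALSE)
  expect_equal(p$length, 31L)
})

test_that("a seed sequence outscores its shuffles against its own profile", {
  path <- system.file("extdata", "seeds", "synthetic_p25_full.fasta",
                      package = "tpppscan")
  seeds <- read_fasta(path, "protein")
  prof <- build_profile(seeds$residues, "p25_full", calibrate = FALSE)
  own <- scan_profile(seeds[1, ], prof, threshold = -Inf)$score[1]
  set.seed(77)
  chars <- strsplit(seeds$residues[1], "")[[1]]
  for (k in 1:100) {
    shuf <- protein_set("shuf", paste(sample(chars), collapse = ""))
    s <- scan_profile(shuf, prof, threshold = -Inf)
    expect_lt(max(c(0, s$score)), own)
  }
})

test_that("a planted seed copy is recovered as one covering hit", {
  profs <- default_profiles()
  path <- system.file("extdata", "seeds", "synthetic_p25_full.fasta",
                      package = "tpppscan")
  seed1 <- read_fasta(path, "protein")$residues[1]
  set.seed(5)
  rec <- protein_set("planted",
                     paste0(rand_protein(40), seed1, rand_protein(30)))
  h <- scan_profile(rec, profs$p25_full)
  expect_equal(nrow(h), 1L)
  ov <- min(h$end, 40 + 160) - max(h$start, 40)
  expect_gte(ov / 160, 0.9)
  expect_gte(h$coverage, 0.9)
})

test_that("two planted cores separated by a linker give two hits", {
  profs <- default_profiles()
  cores <- tpppscan:::synthetic_cores()
  core <- substr(cores[["p25_core"]], 1, 140)
  set.seed(6)
  rec <- protein_set("dup", paste0(core, rand_protein(50), core))
  h <- scan_profile(rec, profs$p25_full)
  expect_equal(nrow(h), 2L)
  expect_true(all(h$end[-nrow(h)] <= h$start[-1]))  # non-overlapping, sorted
})

test_that("hit scores are invariant under appending distant residues; lowering the threshold only adds hits", {
  profs <- default_profiles()
  cores <- tpppscan:::synthetic_cores()
  set.seed(7)
  base <- paste0(rand_protein(20), cores[["p25_core"]])
  h1 <- scan_profile(protein_set("a", base), profs$p25_full)
  h2 <- scan_profile(protein_set("a", paste0(base, rand_protein(60))),
                     profs$p25_full)
  expect_equal(h1$score[1], h2$score[1])
  expect_equal(h1$start[1], h2$start[1])

  lo <- scan_profile(protein_set("a", base), profs$p25_full,
                     threshold = profs$p25_full$threshold / 2)
  expect_true(all(paste(h1$start, h1$end) %in% paste(lo$start, lo$end)))
})

test_that("motif matching follows the degenerate patterns", {
  hits <- find_motifs(protein_set("r", "GAGAGAAGR"),
                      motifs = list(motif_def("rossmann")),
                      placement = "anywhere")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$matched, "GAGAGAAGR")

  yes <- find_motifs(protein_set("s", "VAAAYKKF"),
                     motifs = list(motif_def("start_anchor")),
                     placement = "anywhere")
  expect_equal(nrow(yes), 1L)
  no <- find_motifs(protein_set("s", "AAAAYKKF"),
                    motifs = list(motif_def("start_anchor")),
                    placement = "anywhere")
  expect_equal(nrow(no), 0L)
})

test_that("domain-relative placements need a domain and honor their windows", {
  expect_error(find_motifs(protein_set("x", strrep("A", 50)),
                           motifs = list(motif_def("ggp"))),
               "requires a domain")
  # GGP at domain offset 10 of a 40-residue domain is in the N-terminal half
  rec <- protein_set("x", paste0(strrep("A", 10), "GGP", strrep("A", 27)))
  dom <- data.frame(protein_id = "x", profile_id = "p25_full",
                    start = 0L, end = 40L)
  expect_equal(nrow(find_motifs(rec, list(motif_def("ggp")), domain = dom)), 0L)
  # the same motif planted at offset 25 is in the C-terminal half
  rec2 <- protein_set("x", paste0(strrep("A", 25), "GGP", strrep("A", 12)))
  expect_equal(nrow(find_motifs(rec2, list(motif_def("ggp")), domain = dom)), 1L)
})

test_that("anywhere-placement motif search equals regex brute force", {
  set.seed(88)
  motifs <- default_motifs()
  for (k in 1:25) {
    seq <- rand_protein(200)
    rec <- protein_set("r", seq)
    for (m in motifs) {
      got <- find_motifs(rec, list(m), placement = "anywhere")$start
      expect_equal(got, brute_motif_offsets(seq, m$pattern))
    }
  }
})

test_that("profiles survive a JSON round trip", {
  profs <- default_profiles()
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(profs$dcx, f)
  p2 <- read_profile_json(f)
  expect_equal(p2$profile_id, "dcx")
  expect_equal(p2$threshold, profs$dcx$threshold)
  expect_equal(unname(p2$scores), unname(profs$dcx$scores), tolerance = 1e-12)
})
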