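test_that("consensus scan finds the KKRK core in the monopartite candidate", {
  hits <- scanMonopartiteNLS(ProteinSequence("DEQVKKRKLDY", anchor = 777))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 781L)
  expect_equal(hits$end, 784L)
  expect_equal(hits$matched, "KKRK")
})

test_that("scan handles no-match, overlapping and short inputs", {
  expect_equal(nrow(scanMonopartiteNLS(ProteinSequence("AAAA"))), 0L)
  expect_equal(nrow(scanMonopartiteNLS(ProteinSequence("KKR"))), 0L)
  # SV40 NLS contains two overlapping consensus windows
  sv40 <- scanMonopartiteNLS(ProteinSequence("PKKKRKV", anchor = 126))
  expect_equal(sv40$start, c(127L, 128L))
  expect_equal(sv40$end, c(130L, 131L))
  expect_equal(sv40$matched, c("KKKR", "KKRK"))
})

test_that("scan agrees with the brute-force window oracle on random sequences", {
  set.seed(42)
  for (i in 1:25) {
    res <- randomResidues(200)
    anchor <- sample(1:500, 1)
    hits <- scanMonopartiteNLS(ProteinSequence(res, anchor = anchor))
    expect_identical(hits$start, oracleScanNLS(res, anchor),
                     info = paste("seq", i))
    expect_true(all(hits$end == hits$start + 3L))
    # every reported window really matches, via the stored substring
    expect_true(all(substr(hits$matched, 1, 1) == "K"))
    expect_true(all(substr(hits$matched, 2, 2) %in% c("K", "R")))
    expect_true(all(substr(hits$matched, 4, 4) %in% c("K", "R")))
  }
})

test_that("invalid residues are rejected with the offending position named", {
  expect_error(ProteinSequence("DEQX"), "position 4")
  expect_error(ProteinSequence("B"), "position 1")
  expect_warning(s <- ProteinSequence("kkrk"), "upper-cased")
  expect_equal(residues(s), "KKRK")
})

test_that("deleteSegment excises inclusively and preserves the anchor", {
  cand <- ProteinSequence("DEQVKKRKLDY", id = "cand", anchor = 777)
  nlsd <- deleteSegment(cand, 781, 784)
  expect_equal(residues(nlsd), "DEQVLDY")
  expect_equal(anchor(nlsd), 777L)
  # the deletion removes every consensus match in the candidate window
  expect_equal(nrow(scanMonopartiteNLS(nlsd)), 0L)
  # full-length deletion is an allowed degenerate case
  empty <- deleteSegment(cand, 777, 787)
  expect_equal(nchar(residues(empty)), 0L)
  expect_error(deleteSegment(cand, 770, 780), "outside")
  expect_error(deleteSegment(cand, 786, 790), "outside")
})

test_that("delete then re-insert reconstructs the original sequence", {
  set.seed(7)
  for (i in 1:10) {
    res <- randomResidues(60)
    anchor <- sample(1:100, 1)
    s <- ProteinSequence(res, anchor = anchor)
    a <- sample(anchor:(anchor + 59), 1)
    b <- sample(a:(anchor + 59), 1)
    cut <- substr(res, a - anchor + 1, b - anchor + 1)
    trimmed <- deleteSegment(s, a, b)
    rebuilt <- paste0(
      substr(residues(trimmed), 1, a - anchor),
      cut,
      substr(residues(trimmed), a - anchor + 1, nchar(residues(trimmed)))
    )
    expect_identical(rebuilt, res)
  }
})

test_that("appendSegment is additive and restores a scannable NLS", {
  nlsd <- deleteSegment(ProteinSequence("DEQVKKRKLDY", anchor = 777), 781, 784)
  fused <- appendSegment(nlsd, "PKKKRKV")
  expect_equal(nchar(residues(fused)), nchar(residues(nlsd)) + 7L)
  expect_true(endsWith(residues(fused), "PKKKRKV"))
  hits <- scanMonopartiteNLS(fused)
  tailStart <- anchor(fused) + nchar(residues(nlsd))
  expect_true(any(hits$start >= tailStart))
  expect_identical(residues(appendSegment(nlsd, "")), residues(nlsd))
  expect_error(appendSegment(nlsd, "PK*"), "invalid residue")
  set.seed(11)
  for (i in 1:10) {
    tail <- randomResidues(sample(0:30, 1))
    s <- ProteinSequence(randomResidues(sample(1:50, 1)))
    expect_identical(residues(appendSegment(s, tail)),
                     paste0(residues(s), tail))
  }
})

test_that("FASTA round-trip preserves residues and anchors", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- list(
    ProteinSequence("DEQVKKRKLDY", id = "cand1", anchor = 777),
    ProteinSequence("PKKKRKV", id = "sv40", anchor = 126),
    ProteinSequence("ACDEFGHIKLMNPQRSTVWY", id = "plain")
  )
  writeProteinFasta(seqs, path)
  back <- readProteinFasta(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_identical(residues(back[[i]]), residues(seqs[[i]]))
    expect_identical(anchor(back[[i]]), anchor(seqs[[i]]))
  }
})
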