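test_that("normalization maps DNA to RNA alphabet and folds case", {
  expect_equal(normalize_sequence("m1", "TTAGG", "mRNA")$residues, "UUAGG")
  expect_equal(normalize_sequence("m2", "AUCG", "miRNA")$residues, "AUCG")
  expect_equal(normalize_sequence("m3", "aUcG", "miRNA")$residues, "AUCG")
  expect_equal(normalize_sequence("m4", "AU CG\n", "miRNA")$residues, "AUCG")
  expect_equal(normalize_sequence("m5", "AUCG", "mRNA")$role, "mRNA")
})

test_that("ambiguity codes are rejected with the offending position", {
  expect_error(normalize_sequence("x", "AUNCG", "miRNA"), "position 3")
  expect_error(normalize_sequence("x", "", "miRNA"))
  expect_error(normalize_sequence("x", "  ", "miRNA"))
})

test_that("orientation reversal is plain character reversal", {
  r <- normalize_sequence("g", "AUCG", "mRNA")
  expect_equal(reverse_orientation(r)$residues, "GCUA")
  expect_equal(reverse_orientation(reverse_orientation(r))$residues, "AUCG")
  pal <- normalize_sequence("p", "AUUA", "mRNA")
  expect_equal(reverse_orientation(pal)$residues, "AUUA")
  # no complementation, residue multiset preserved
  long <- normalize_sequence("l", "AAACCGU", "mRNA")
  rev <- reverse_orientation(long)
  expect_equal(sort(strsplit(rev$residues, "")[[1]]),
               sort(strsplit(long$residues, "")[[1]]))
  mi <- normalize_sequence("mi", "AUCG", "miRNA")
  expect_error(reverse_orientation(mi), "mRNA")
})

test_that("fragmentation covers the sequence with overlapping windows", {
  short <- normalize_sequence("s", strrep("A", 150), "mRNA")
  fs <- fragment_mrna(short, seed = 1)
  expect_equal(nrow(fs$fragments), 1L)
  expect_equal(c(fs$fragments$start, fs$fragments$end), c(0L, 150L))

  # forced fragment length: min = max = 400, overlap 100
  r600 <- normalize_sequence("r", strrep("ACGU", 150), "mRNA")
  fs2 <- fragment_mrna(r600, min_len = 400, max_len = 400, overlap = 100,
                       seed = 1)
  expect_equal(fs2$fragments$start, c(0L, 300L))
  expect_equal(fs2$fragments$end, c(400L, 600L))

  # coverage + overlap invariants across random lengths and seeds
  set.seed(42)
  for (i in 1:20) {
    L <- sample(150:2500, 1)
    rec <- normalize_sequence("x", paste(
      sample(c("A", "C", "G", "U"), L, TRUE), collapse = ""), "mRNA")
    fs <- fragment_mrna(rec, seed = i)
    fr <- fs$fragments
    expect_equal(fr$start[1], 0L)
    expect_equal(fr$end[nrow(fr)], L)
    expect_equal(fr$residues,
                 substring(rec$residues, fr$start + 1L, fr$end))
    if (nrow(fr) > 1) {
      expect_true(all(fr$start[-1] < fr$end[-nrow(fr)]))  # >= 1 nt overlap
      len_fr <- fr$end - fr$start
      expect_true(all(len_fr[-length(len_fr)] >= 200))
      expect_true(all(len_fr <= 400))
      expect_gt(len_fr[length(len_fr)], 100)  # truncated tail beats overlap
    }
  }
  expect_error(fragment_mrna(short, overlap = 250), "overlap")
})

test_that("k-mer tokenization yields L - k + 1 ordered tokens", {
  expect_equal(tokenize_kmers("AAAAAA", 6), "AAAAAA")
  expect_length(tokenize_kmers("AUCGAUCGAU", 6), 5L)
  expect_equal(tokenize_kmers("AUCG", 2), c("AU", "UC", "CG"))
  expect_error(tokenize_kmers("AUC", 6), "too short")
  set.seed(1)
  for (i in 1:10) {
    L <- sample(6:60, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    expect_length(tokenize_kmers(s, 6), L - 5L)
  }
})

test_that("vocabulary is the complete lexicographic k-mer set", {
  v6 <- build_vocabulary(6)
  expect_length(v6$tokens, 4096L)
  expect_equal(build_vocabulary(1)$tokens, c("A", "C", "G", "U"))
  v2 <- build_vocabulary(2)
  expect_length(v2$tokens, 16L)
  expect_equal(v2$tokens, sort(v2$tokens))
  expect_false(anyDuplicated(v6$tokens) > 0)
  # index is the inverse of the token list
  idx <- kmer_index(v6, v6$tokens[c(1, 100, 4096)])
  expect_equal(idx, c(0L, 99L, 4095L))
  expect_equal(kmer_index(v2, v2$tokens), 0:15)
  expect_error(build_vocabulary(0))
})

test_that("FASTA round trip preserves ids and normalized residues", {
  recs <- random_records(2, 2, seed = 3)
  tmp <- tempfile(fileext = ".fasta")
  write_fasta_records(recs, tmp)
  back <- read_fasta_records(tmp, "miRNA")
  expect_equal(vapply(back, function(r) r$id, ""),
               vapply(recs, function(r) r$id, ""))
  expect_equal(vapply(back, function(r) r$residues, ""),
               vapply(recs, function(r) r$residues, ""))
  # DNA-alphabet file is normalized on read
  writeLines(c(">seq1 some description", "ttAGC", "GGT"), tmp)
  r <- read_fasta_records(tmp, "mRNA")
  expect_equal(r[[1]]$id, "seq1")
  expect_equal(r[[1]]$residues, "UUAGCGGU")
})

test_that("fragment sets export as BED-like TSV", {
  rec <- normalize_sequence("tx1", strrep("ACGU", 120), "mRNA")
  fs <- fragment_mrna(rec, seed = 2)
  tmp <- tempfile(fileext = ".tsv")
  write_fragments_tsv(fs, tmp)
  df <- read.table(tmp, sep = "\t")
  expect_equal(df[[1]][1], "tx1")
  expect_equal(df[[2]], fs$fragments$start)
  expect_equal(df[[3]], fs$fragments$end)
})
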