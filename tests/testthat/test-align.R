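test_that("self-alignment scores are sums of diagonal matrix entries", {
  scheme <- scoring_scheme()
  hit <- local_align("ARN", "ARN", scheme)
  # BLOSUM62 diagonal: A=4, R=5, N=6
  expect_equal(hit$raw_score, 15)
  expect_equal(hit$bit_score, (0.267 * 15 - log(0.041)) / log(2))
  expect_equal(hit$evalue, 9 * 2^(-hit$bit_score))
})

test_that("no positive-scoring pair yields the empty local alignment", {
  hit <- local_align("AAAA", "PPPP", scoring_scheme())
  expect_equal(hit$raw_score, 0)
})

test_that("e-values follow the closed Karlin-Altschul form", {
  expect_equal(evalue(0, 100, 100), 10000)
  expect_equal(evalue(10, 100, 100), 10000 / 1024)
  expect_equal(evalue(7, 200, 100), 2 * evalue(7, 100, 100))  # linear in m
})

test_that("Smith-Waterman matches the exhaustive-enumeration oracle", {
  scheme <- scoring_scheme()
  set.seed(991)
  for (i in seq_len(80)) {
    a <- random_protein(sample(1:10, 1))
    b <- random_protein(sample(1:10, 1))
    want <- sw_oracle(a, b, scheme$matrix, scheme$gap_open, scheme$gap_extend)
    expect_equal(local_align(a, b, scheme)$raw_score, want,
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric and monotone under extension", {
  scheme <- scoring_scheme()
  set.seed(992)
  for (i in seq_len(20)) {
    a <- random_protein(sample(3:25, 1))
    b <- random_protein(sample(3:25, 1))
    s_ab <- local_align(a, b, scheme)$raw_score
    expect_equal(s_ab, local_align(b, a, scheme)$raw_score)
    ext <- random_protein(5)
    expect_gte(local_align(paste0(a, ext), paste0(b, ext), scheme)$raw_score,
               s_ab)
  }
})

test_that("X scores zero against everything", {
  scheme <- scoring_scheme()
  expect_equal(local_align("XXXX", "ARND", scheme)$raw_score, 0)
  # an interior X contributes nothing but does not break the alignment
  s_plain <- local_align("ARNDCQEG", "ARNDCQEG", scheme)$raw_score
  s_with_x <- local_align("ARNXCQEG", "ARNDCQEG", scheme)$raw_score
  expect_equal(s_with_x, s_plain - scheme$matrix["D", "D"])
})

test_that("search_database orders hits and honors exclusions", {
  set.seed(993)
  db <- protein_set(c("s1", "s2", "s3"),
                    c(random_protein(40), random_protein(40),
                      random_protein(40)))
  scheme <- scoring_scheme()
  hits <- search_database(db$residues[2], db, scheme, query_id = "q")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$subject_id[1], "s2")  # self-similarity ranks first
  expect_true(all(diff(hits$bit_score) <= 0))
  hits2 <- search_database(db$residues[2], db, scheme, exclude_ids = "s2")
  expect_equal(nrow(hits2), 2L)
  expect_false("s2" %in% hits2$subject_id)
  empty <- db[0, ]
  class(empty) <- c("protein_set", "data.frame")
  expect_equal(nrow(search_database("ARN", empty, scheme)), 0L)
})

test_that("NCBI matrix text format round-trips and matches BLOSUM62", {
  scheme <- scoring_scheme()
  f <- withr::local_tempfile(fileext = ".txt")
  write_score_matrix(scheme$matrix, f)
  back <- read_score_matrix(f)
  expect_equal(back, scheme$matrix)
  # cross-check the default against the independently shipped Biostrings copy
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- rownames(scheme$matrix)[rownames(scheme$matrix) != "X"]
  expect_equal(scheme$matrix[aa, aa],
               BLOSUM62[aa, aa])
  expect_true(all(scheme$matrix["X", ] == 0))
})

test_that("external BLAST+ backend agrees with the internal engine", {
  if (!nzchar(Sys.which("blastp")) || !nzchar(Sys.which("makeblastdb"))) {
    succeed("BLAST+ binaries not on PATH; backend not exercised")
    return(invisible())
  }
  ds <- tiny_dataset()
  db <- ds$seqs[1:10, ]
  class(db) <- c("protein_set", "data.frame")
  scheme <- scoring_scheme()
  query <- ds$seqs$residues[11]
  internal <- search_database(query, db, scheme)
  external <- blast_backend_scores(query, db)
  shared <- intersect(internal$subject_id, external$subject_id)
  expect_gte(length(shared), 5L)
  rel <- abs(external$bit_score[match(shared, external$subject_id)] -
             internal$bit_score[match(shared, internal$subject_id)]) /
    internal$bit_score[match(shared, internal$subject_id)]
  expect_lt(max(rel), 0.10)
})
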