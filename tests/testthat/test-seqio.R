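test_that("read_fasta parses records in file order and normalizes case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 first protein", "arnDCq", ">seq2", "MKV", "LLA"), f)
  ps <- read_fasta(f)
  expect_s3_class(ps, "protein_set")
  expect_equal(ps$id, c("seq1", "seq2"))
  expect_equal(ps$residues, c("ARNDCQ", "MKVLLA"))  # uppercased, unwrapped
  expect_equal(ps$description[1], "first protein")
})

test_that("read_fasta rejects malformed records with the record index", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ARN", ">bad", "AR9N"), f)
  expect_error(read_fasta(f), "record 2")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">empty", "", ">ok", "ARN"), f2)
  expect_error(read_fasta(f2), "record 1")
  expect_error(read_fasta(withr::local_tempfile()), "not found")
})

test_that("ambiguity codes map to X with a warning", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">amb", "ARBZU*N"), f)
  expect_warning(ps <- read_fasta(f), "non-standard")
  expect_equal(ps$residues, "ARXXXXN")
})

test_that("write_fasta / read_fasta round-trips normalized records", {
  ps <- protein_set(c("a", "b"), c("MKVARNDC", random_protein(130)),
                    description = c("alpha", ""))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ps, f)
  back <- read_fasta(f)
  expect_equal(back$id, ps$id)
  expect_equal(back$residues, ps$residues)
  expect_equal(back$description[1], "alpha")
})

test_that("load_labeled_dataset reports the reference per-class counts", {
  # the eight-class reference layout: 85 sequences, counts 13/9/10/10/14/8/14/7
  counts <- c(A = 13, B12 = 9, B34 = 10, BPI = 10, C = 14, D = 8, E = 14,
              AGL6 = 7)
  dir <- withr::local_tempdir()
  set.seed(11)
  fix <- write_reference_fixture(dir, as.list(counts))
  ds <- load_labeled_dataset(fix$fasta, fix$manifest, name = "ref85")
  expect_equal(nrow(ds$seqs), 85L)
  expect_equal(class_counts(ds), counts)
  # deterministic and order-stable
  ds2 <- load_labeled_dataset(fix$fasta, fix$manifest, name = "ref85")
  expect_identical(ds$seqs, ds2$seqs)
  expect_identical(ds$labels, ds2$labels)
})

test_that("manifest validation catches bad labels and unjoined ids", {
  dir <- withr::local_tempdir()
  set.seed(12)
  fix <- write_reference_fixture(dir, list(A = 2))
  man <- utils::read.delim(fix$manifest, colClasses = "character")
  man$class[1] <- "B"  # must be B12/B34/BPI
  bad <- file.path(dir, "bad.tsv")
  utils::write.table(man, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(load_labeled_dataset(fix$fasta, bad), error = identity)
  expect_match(conditionMessage(err), "unknown class")
  expect_match(conditionMessage(err), "B12, B34, BPI")

  man2 <- utils::read.delim(fix$manifest, colClasses = "character")
  man2$sequence_id[2] <- "ghost"
  bad2 <- file.path(dir, "bad2.tsv")
  utils::write.table(man2, bad2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_labeled_dataset(fix$fasta, bad2, require_all_classes = FALSE),
               "ghost")
})

test_that("manifest domain spans parse to 0-based half-open annotations", {
  dir <- withr::local_tempdir()
  seqs <- protein_set("s1", random_protein(80))
  fasta <- file.path(dir, "one.fasta")
  write_fasta(seqs, fasta)
  manifest <- file.path(dir, "one.tsv")
  utils::write.table(
    data.frame(sequence_id = "s1", class = "A", domains = "M:0-60;K:65-80"),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- load_labeled_dataset(fasta, manifest, require_all_classes = FALSE)
  ann <- ds$annotations[["s1"]]
  expect_equal(ann$spans$M, c(0L, 60L))
  expect_equal(ann$spans$K, c(65L, 80L))
  expect_true(ann$is_mikc)
})

test_that("labeled datasets round-trip through FASTA + manifest", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_labeled_dataset(ds, file.path(dir, "d.fasta"), file.path(dir, "d.tsv"))
  back <- load_labeled_dataset(file.path(dir, "d.fasta"),
                               file.path(dir, "d.tsv"))
  expect_equal(back$seqs$residues, ds$seqs$residues)
  expect_equal(unname(back$labels), unname(ds$labels))
  expect_equal(back$annotations[[ds$seqs$id[1]]]$spans,
               ds$annotations[[ds$seqs$id[1]]]$spans)
})
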