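# Shared fixtures, built in code. The full benchmark system is expensive
# (~half a minute) and is cached for the whole test run.

.madsbox_test_cache <- new.env(parent = emptyenv())

# the default study conditions: 8 classes x 10 members, fixed seed
benchmark_seed <- 101L

get_benchmark_bundle <- function() {
  if (is.null(.madsbox_test_cache$bundle)) {
    .madsbox_test_cache$bundle <-
      benchmark_bundle(family_spec(seed = benchmark_seed))
  }
  .madsbox_test_cache$bundle
}

get_benchmark_system <- function() {
  if (is.null(.madsbox_test_cache$system)) {
    bundle <- get_benchmark_bundle()
    .madsbox_test_cache$system <-
      suppressWarnings(mads_train(bundle$train, seed = benchmark_seed))
  }
  .madsbox_test_cache$system
}

# small labeled dataset for fast unit tests (class completeness holds)
tiny_dataset <- function(n_per_class = 3L, seed = 7L) {
  generate_families(family_spec(n_per_class = n_per_class, seed = seed))
}

# residues drawn from coil-neutral letters, for constructs whose planted
# coiled-coil boundary must stay identifiable
neutral_residues <- function(n) {
  paste(sample(c("S", "T", "N", "Q", "G", "P", "D", "H", "R"), n,
               replace = TRUE), collapse = "")
}

# a concrete instantiation of the default M-domain pattern
m_pattern_example <- "KRIENKINRQVTFSKRR"

ideal_heptads <- function(n_heptads = 4L) {
  paste(rep("LEALEGK", n_heptads), collapse = "")
}

# write a FASTA/manifest pair of random sequences with given class counts
write_reference_fixture <- function(dir, counts, len = 60L) {
  ids <- unlist(lapply(names(counts), function(cls) {
    sprintf("%s_%02d", cls, seq_len(counts[[cls]]))
  }))
  classes <- rep(names(counts), unlist(counts))
  seqs <- protein_set(ids, vapply(seq_along(ids), function(i)
    random_protein(len), character(1)))
  fasta <- file.path(dir, "ref.fasta")
  manifest <- file.path(dir, "ref.tsv")
  write_fasta(seqs, fasta)
  utils::write.table(
    data.frame(sequence_id = ids, class = classes),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, manifest = manifest, ids = ids, classes = classes)
}
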