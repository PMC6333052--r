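test_that("reference databases restrict by region and keep all classes", {
  ds <- tiny_dataset()
  refdbs <- build_reference_databases(ds)
  expect_setequal(names(refdbs), region_tags())
  n_whole <- sum(vapply(refdbs$WHOLE$per_class, nrow, integer(1)))
  expect_equal(n_whole, nrow(ds$seqs))
  # a sequence annotated without K drops from the K database only
  ds2 <- ds
  id1 <- ds2$seqs$id[1]
  sp <- ds2$annotations[[id1]]$spans
  sp$K <- NULL; sp$I <- NULL; sp$C_TERM <- NULL
  ds2$annotations[[id1]] <- domain_annotation(id1, sp, 300L)
  refdbs2 <- build_reference_databases(ds2)
  expect_false(id1 %in% refdbs2$K$per_class[["A"]]$id)
  expect_true(id1 %in% refdbs2$WHOLE$per_class[["A"]]$id)
  expect_true(id1 %in% refdbs2$M$per_class[["A"]]$id)
})

test_that("degenerate training sets are rejected", {
  ds <- tiny_dataset()
  keep <- ds$seqs$id[ds$labels != "D"]
  sub <- subset_dataset(ds, keep)
  expect_error(build_reference_databases(sub), "missing class.*D")
  empty <- subset_dataset(ds, character(0))
  expect_error(build_reference_databases(empty), "empty|missing")
})

test_that("similarity gate: zero without passing hits, self bit score on an
           exact copy, zero on self-excluded singleton", {
  scheme <- scoring_scheme()
  set.seed(31)
  query <- random_protein(80)
  # databases of short unrelated sequences: nothing passes the gate
  far_db <- structure(list(region = "WHOLE", per_class = stats::setNames(
    lapply(gene_classes(), function(cl)
      protein_set(paste0(cl, "_1"), strrep("G", 15))), gene_classes())),
    class = "ref_database")
  v <- encode_class_similarity(query, far_db, scheme)
  expect_equal(unname(as.numeric(v)), rep(0, 8))

  # class C holds an exact copy of the query: its feature equals the
  # self-alignment bit score; other classes stay 0
  copy_db <- far_db
  copy_db$per_class[["C"]] <- protein_set("copy", query)
  v2 <- encode_class_similarity(query, copy_db, scheme)
  self_bits <- local_align(query, query, scheme)$bit_score
  expect_equal(unname(v2[["C"]]), self_bits)
  expect_equal(sum(as.numeric(v2) != 0), 1L)

  # encoding a reference against its own singleton class with
  # self-exclusion leaves an empty comparison set
  v3 <- encode_class_similarity(query, copy_db, scheme,
                                exclude_self_id = "copy")
  expect_equal(unname(v3[["C"]]), 0)
})

test_that("similarity features are permutation-invariant and monotone in
           the e-value threshold", {
  set.seed(32)
  ds <- tiny_dataset()
  refdbs <- build_reference_databases(ds)
  scheme <- scoring_scheme()
  query <- ds$seqs$residues[5]
  v <- encode_class_similarity(query, refdbs$WHOLE, scheme)
  shuffled <- refdbs$WHOLE
  shuffled$per_class <- lapply(shuffled$per_class, function(ps) {
    idx <- sample(nrow(ps))
    out <- ps[idx, , drop = FALSE]
    class(out) <- c("protein_set", "data.frame")
    out
  })
  expect_equal(as.numeric(encode_class_similarity(query, shuffled, scheme)),
               as.numeric(v))
  loose <- encode_class_similarity(query, refdbs$WHOLE, scheme,
                                   evalue_threshold = 1e-2)
  strict <- encode_class_similarity(query, refdbs$WHOLE, scheme,
                                    evalue_threshold = 1e-30)
  expect_true(all(as.numeric(loose) >= as.numeric(v) |
                  as.numeric(loose) == 0))
  # relaxing the threshold never zeroes a passing class
  expect_true(all((as.numeric(v) > 0) <= (as.numeric(loose) > 0)))
  expect_true(all((as.numeric(strict) > 0) <= (as.numeric(v) > 0)))
})

test_that("BindN-style M encoding has fixed layout with padding", {
  full <- encode_bindn_block(random_protein(57))
  expect_length(full, 171L)
  expect_true(all(full >= 0 & full <= 1))
  short <- encode_bindn_block(random_protein(50))
  expect_length(short, 171L)
  expect_equal(short[(150 + 1):171], rep(0, 21))
  ala <- encode_bindn_block(strrep("A", 57))
  expect_equal(unique(round(ala[seq(1, 171, 3)], 12)), ala[1])
  x_enc <- encode_bindn_block(strrep("X", 3))
  scales <- madsbox:::bindn_scales()
  expect_equal(x_enc[1:3], unname(vapply(scales, mean, numeric(1))))
  expect_error(encode_bindn_block(""), "empty")
})

test_that("build_feature_vector concatenates blocks per recipe", {
  ds <- tiny_dataset()
  refdbs <- build_reference_databases(ds)
  id <- ds$seqs$id[1]
  res <- ds$seqs$residues[1]
  ann <- ds$annotations[[id]]
  configs <- default_configs()
  fv_whole <- build_feature_vector(res, ann, "WHOLE-sim", refdbs,
                                   configs = configs)
  expect_length(fv_whole, 8L)
  fv_mb <- build_feature_vector(res, ann, "M-sim+BindN", refdbs,
                                configs = configs)
  expect_length(fv_mb, 8L + 171L)
  expect_equal(recipe_feature_length("M-sim+BindN"), 179L)
  # an M-only fragment cannot feed a K recipe
  frag <- truncate_to_domains(res, ann, "M")
  expect_error(
    build_feature_vector(frag$residues, frag$annotation, "K-sim+COILS",
                         refdbs, configs = configs),
    "region unavailable: K")
})

test_that("feature blocks are deterministic functions of their inputs", {
  ds <- tiny_dataset()
  refdbs <- build_reference_databases(ds)
  configs <- default_configs()
  id <- ds$seqs$id[3]
  args <- list(ds$seqs$residues[3], ds$annotations[[id]], "K-sim+COILS",
               refdbs, scoring_scheme(), configs)
  expect_identical(do.call(build_feature_vector, args),
                   do.call(build_feature_vector, args))
})

test_that("sparse SVM text export writes 1-based nonzero entries", {
  x <- matrix(c(0, 1.5, 0, 2, 0, 0), nrow = 2, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  write_svm_format(x, c("A", "B12"), f)
  lines <- readLines(f)
  expect_equal(lines[1], "1 2:1.5")
  expect_equal(lines[2], "2 1:2")
})
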