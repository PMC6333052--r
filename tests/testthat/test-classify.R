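# a tiny crafted feature problem: one informative column per class plus
# noise, trivially separable
crafted_features <- function(n_per_class = 8L, noise = 0.05, seed = 61L) {
  withr::with_seed(seed, {
    labels <- rep(gene_classes(), each = n_per_class)
    x <- matrix(stats::rnorm(length(labels) * 8L, sd = noise),
                ncol = 8L,
                dimnames = list(sprintf("s%02d", seq_along(labels)),
                                paste0("sim:WHOLE:", gene_classes())))
    for (i in seq_along(labels)) {
      x[i, paste0("sim:WHOLE:", labels[i])] <- 1 +
        stats::rnorm(1, sd = noise)
    }
    list(x = x, labels = stats::setNames(labels, rownames(x)))
  })
}

crafted_dataset <- function(cf) {
  seqs <- protein_set(names(cf$labels),
                      vapply(seq_along(cf$labels), function(i)
                        random_protein(30), character(1)))
  anns <- stats::setNames(lapply(names(cf$labels), function(id)
    domain_annotation(id, list(M = c(0, 5), I = c(5, 10), K = c(10, 20),
                               C_TERM = c(20, 30)), 30L)), names(cf$labels))
  labeled_dataset("crafted", seqs, cf$labels, anns)
}

fast_hyper <- default_hyper(cost = c(1, 8), gamma = c(0.125, 1))

test_that("exactly nine recipes are registered with unique ids", {
  recipes <- registered_recipes()
  expect_length(recipes, 9L)
  ids <- vapply(recipes, `[[`, character(1), "recipe_id")
  expect_false(anyDuplicated(ids) > 0)
  mb <- recipes[[which(ids == "M-sim+BindN")]]
  expect_equal(mb$required_regions, "M")
  expect_equal(get_recipe("WHOLE-sim")$required_regions,
               c("M", "I", "K", "C_TERM"))
  expect_error(get_recipe("nope"), "unknown recipe")
})

test_that("train_model reaches perfect CV on separable features and is
           deterministic", {
  set.seed(62)
  cf <- crafted_features()
  ds <- crafted_dataset(cf)
  refdbs <- build_reference_databases(ds)
  m <- train_model(ds, "WHOLE-sim", refdbs, hyper = fast_hyper, seed = 9L,
                   features = cf$x)
  expect_equal(m$cv_accuracy, 1.0)
  m2 <- train_model(ds, "WHOLE-sim", refdbs, hyper = fast_hyper, seed = 9L,
                    features = cf$x)
  probe <- madsbox:::apply_scaler(cf$x[1:5, , drop = FALSE], m$scaler,
                                  clamp = TRUE)
  expect_identical(madsbox:::model_probs(m, probe),
                   madsbox:::model_probs(m2, probe))
})

test_that("shuffled labels drop CV accuracy to chance level", {
  cf <- crafted_features()
  shuffled <- withr::with_seed(63L, {
    stats::setNames(sample(cf$labels), names(cf$labels))
  })
  ds <- crafted_dataset(list(x = cf$x, labels = shuffled))
  refdbs <- build_reference_databases(ds)
  m <- train_model(ds, "WHOLE-sim", refdbs, hyper = fast_hyper, seed = 9L,
                   features = cf$x)
  # chance = 1/8; 3 sigma of binomial noise at n = 64
  sigma <- sqrt(0.125 * 0.875 / 64)
  expect_lt(m$cv_accuracy, 0.125 + 3 * sigma)
})

test_that("degenerate class sizes are rejected", {
  cf <- crafted_features(n_per_class = 2L)
  ds <- crafted_dataset(cf)
  keep <- names(cf$labels)[c(1, 3:16)]  # class A left with one member
  expect_error(
    train_model(subset_dataset(ds, keep), "WHOLE-sim",
                build_reference_databases(ds), hyper = fast_hyper,
                features = cf$x[keep, ]),
    "degenerate")
})

test_that("cross_validate is stratified, reproducible and leakage-free", {
  ds <- tiny_dataset(n_per_class = 4L)
  res <- suppressWarnings(
    cross_validate(ds, "C-sim", k = 3L, seed = 5L, hyper = fast_hyper,
                   details = TRUE))
  expect_length(res$fold_accuracy, 3L)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  res2 <- suppressWarnings(
    cross_validate(ds, "C-sim", k = 3L, seed = 5L, hyper = fast_hyper,
                   details = TRUE))
  expect_identical(res$folds, res2$folds)
  expect_identical(res$fold_accuracy, res2$fold_accuracy)
  # no fold leakage: per-fold reference databases exclude the test fold
  for (f in seq_len(3L)) {
    test_ids <- names(res$folds)[res$folds == f]
    expect_length(intersect(res$fold_refdb_ids[[f]], test_ids), 0L)
  }
})

test_that("select_model routes by feasibility then CV accuracy", {
  mk_model <- function(id, required, acc) {
    structure(list(recipe = structure(list(recipe_id = id,
                                           required_regions = required,
                                           blocks = "sim:WHOLE"),
                                      class = "model_recipe"),
                   cv_accuracy = acc), class = "trained_model")
  }
  models <- list(
    mk_model("WHOLE-sim", c("M", "I", "K", "C_TERM"), 0.9),
    mk_model("M-sim", "M", 0.8),
    mk_model("K-sim", "K", 0.95))
  full <- domain_annotation("q", list(M = c(0, 10), I = c(10, 20),
                                      K = c(20, 40), C_TERM = c(40, 50)), 50L)
  expect_equal(select_model(full, models)$recipe$recipe_id, "K-sim")
  m_only <- domain_annotation("q", list(M = c(0, 10)), 10L)
  expect_equal(select_model(m_only, models)$recipe$recipe_id, "M-sim")
  # ties break by registration order
  models_tie <- list(mk_model("M-sim", "M", 0.8), mk_model("M-BindN", "M", 0.8))
  expect_equal(select_model(m_only, models_tie)$recipe$recipe_id, "M-sim")
  non_mikc <- domain_annotation("q", list(), 10L)
  expect_error(select_model(non_mikc, models), "not MIKC-type")
  # MIKC-positive query whose regions satisfy no model
  expect_error(select_model(m_only, list(mk_model("I-sim", "I", 0.9))),
               "no feasible model")
})

test_that("confidences are normalized probabilities with first-max ties", {
  system <- get_benchmark_system()
  bundle <- get_benchmark_bundle()
  preds <- mads_predict(system, bundle$test_full$seqs[1:6, ])
  conf <- as.matrix(preds[, paste0("conf_", gene_classes())])
  expect_true(all(abs(rowSums(conf) - 1) < 1e-6))
  expect_equal(preds$predicted,
               gene_classes()[apply(conf, 1, which.max)])
})

test_that("routing never selects a model requiring an absent region", {
  system <- get_benchmark_system()
  bundle <- get_benchmark_bundle()
  set.seed(64)
  ids <- sample(bundle$full$seqs$id, 12)
  keeps <- list("M", c("M", "I"), c("M", "I", "K"),
                c("M", "I", "K", "C_TERM"), c("K", "C_TERM"), "C_TERM")
  for (id in ids) {
    i <- match(id, bundle$full$seqs$id)
    keep <- keeps[[sample(length(keeps), 1)]]
    frag <- truncate_to_domains(bundle$full$seqs$residues[i],
                                bundle$full$annotations[[id]], keep)
    qs <- protein_set(id, frag$residues, normalize = FALSE)
    row <- mads_predict(system, qs)
    if (row$rejected) {
      expect_false(grepl("M", row$domain_content))
    } else {
      model <- system$models[[row$model_used]]
      ann <- annotate_domains(frag$residues, system$configs$scan, id)
      expect_true(all(model$recipe$required_regions %in%
                      regions_present(ann)))
    }
  }
})

test_that("accuracy arithmetic matches the published percent convention", {
  mk_preds <- function(n, n_correct) {
    truth <- stats::setNames(rep(gene_classes(), length.out = n),
                             sprintf("g%02d", seq_len(n)))
    predicted <- unname(truth)
    wrong <- seq_len(n - n_correct)
    if (length(wrong)) {
      predicted[wrong] <- gene_classes()[(match(predicted[wrong],
                                                gene_classes())) %% 8 + 1]
    }
    conf <- matrix(1 / 8, nrow = n, ncol = 8,
                   dimnames = list(NULL, paste0("conf_", gene_classes())))
    preds <- cbind(data.frame(sequence_id = names(truth),
                              domain_content = "MIKC", model_used = "WHOLE-sim",
                              predicted = predicted, rejected = FALSE,
                              stringsAsFactors = FALSE),
                   as.data.frame(conf))
    list(preds = preds, truth = truth)
  }
  p1 <- mk_preds(26, 24)
  rep1 <- evaluate_predictions(p1$preds, p1$truth)
  expect_equal(rep1$accuracy_pct, 92.31)
  p2 <- mk_preds(15, 14)
  expect_equal(evaluate_predictions(p2$preds, p2$truth)$accuracy_pct, 93.33)
  p3 <- mk_preds(16, 16)
  rep3 <- evaluate_predictions(p3$preds, p3$truth)
  expect_equal(rep3$accuracy_pct, 100)
  expect_equal(sum(rep3$confusion) - sum(diag(rep3$confusion)), 0L)
  # rendered table carries two-decimal confidences
  tab <- format_prediction_table(rep3)
  expect_true(all(grepl("^[01]\\.[0-9]{2}$", tab$A)))
})
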