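# fast combined similarity: one vectorized alignment pass over all eight
# class databases of a region, then per-class means of passing hits
region_sim_features <- function(qseq, refdb, scheme, exclude_self_id,
                                evalue_threshold) {
  ids <- unlist(lapply(refdb$per_class, function(ps) ps$id), use.names = FALSE)
  res <- unlist(lapply(refdb$per_class, function(ps) ps$residues),
                use.names = FALSE)
  cls <- rep(gene_classes(),
             vapply(refdb$per_class, nrow, integer(1)))
  keep <- !(ids %in% (exclude_self_id %||% character(0)))
  ids <- ids[keep]; res <- res[keep]; cls <- cls[keep]
  out <- stats::setNames(numeric(8L), gene_classes())
  if (!length(ids)) return(out)
  raw <- sw_raw_scores(qseq, res, scheme)
  bits <- bit_score(raw, scheme)
  ev <- evalue(bits, nchar(qseq), nchar(res))
  pass <- ev < evalue_threshold
  for (cl in gene_classes()) {
    sel <- pass & cls == cl
    if (any(sel)) out[[cl]] <- mean(bits[sel])
  }
  out
}

# full 214-column feature matrix (5 regions x 8 similarity + 171 bindn +
# 3 coils); NA where a region is absent from the sequence's annotation
feature_matrix <- function(dataset, annotations, refdbs, scheme, configs,
                           self_exclude = TRUE) {
  ids <- dataset$seqs$id
  sim_cols <- as.vector(t(outer(region_tags(), gene_classes(),
                                function(r, c) paste0("sim:", r, ":", c))))
  bindn_cols <- paste0("bindn:", seq_len(3L * configs$m_length))
  coils_cols <- c("coils:mean", "coils:max", "coils:frac50")
  mat <- matrix(NA_real_, nrow = length(ids),
                ncol = length(sim_cols) + length(bindn_cols) + 3L,
                dimnames = list(ids, c(sim_cols, bindn_cols, coils_cols)))
  for (i in seq_along(ids)) {
    id <- ids[i]
    ann <- annotations[[id]]
    seqres <- dataset$seqs$residues[i]
    excl <- if (self_exclude) id else NULL
    for (region in region_tags()) {
      qseq <- region_subsequence(seqres, ann, region)
      if (region == "WHOLE" &&
          !all(region_tags(FALSE) %in% names(ann$spans))) next
      if (is.na(qseq)) next
      v <- region_sim_features(qseq, refdbs[[region]], scheme, excl,
                               configs$evalue_threshold)
      mat[i, paste0("sim:", region, ":", gene_classes())] <- v
    }
    if ("M" %in% names(ann$spans)) {
      mat[i, bindn_cols] <- encode_bindn_block(
        region_subsequence(seqres, ann, "M"), configs$m_length)
    }
    if ("K" %in% names(ann$spans)) {
      prof <- coils_profile(seqres, configs$coils)
      mat[i, coils_cols] <- encode_coils_block(prof, ann$spans$K)
    }
  }
  mat
}

recipe_columns <- function(recipe, configs) {
  unlist(lapply(recipe$blocks, function(b) {
    if (startsWith(b, "sim:")) paste0(b, ":", gene_classes())
    else if (b == "bindn") paste0("bindn:", seq_len(3L * configs$m_length))
    else c("coils:mean", "coils:max", "coils:frac50")
  }), use.names = FALSE)
}

#' Default SVM hyperparameter grid
#'
#' Coarse log-2 grid: cost over 2^-5..2^15, gamma over 2^-15..2^3, in
#' steps of 2^4; selected by 3-fold cross-validated accuracy.
#'
#' @param cost,gamma candidate values.
#' @param inner_k folds of the selection CV.
#' @return List of grid settings.
#' @export
default_hyper <- function(cost = 2^seq(-5, 15, by = 4),
                          gamma = 2^c(seq(-15, 1, by = 4), 3),
                          inner_k = 3L) {
  list(cost = cost, gamma = gamma, inner_k = as.integer(inner_k))
}

# stratified fold assignment; falls back to a plain shuffle (with a
# warning) when some class has fewer members than k
make_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    n <- length(labels)
    counts <- table(labels)
    if (any(counts < k)) {
      warning("class(es) with fewer than ", k,
              " members; falling back to non-stratified folds", call. = FALSE)
      return(sample(rep_len(seq_len(k), n)))
    }
    folds <- integer(n)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
}

fit_scaler <- function(x) {
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  list(min = mins, range = pmax(maxs - mins, 0))
}

apply_scaler <- function(x, scaler, clamp = FALSE) {
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  out[, scaler$range == 0] <- 0
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

svm_fit <- function(x, y, cost, gamma, probability = FALSE, seed = 1L) {
  y <- droplevels(y)
  withr::with_seed(seed, {
    e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE,
               probability = probability)
  })
}

# Grid search by CV accuracy. Combos tied on accuracy are re-scored by
# the cross-validated mean probability assigned to the true class:
# under-regularized winners can tie on hard class predictions while
# producing nearly flat pairwise-coupled probabilities, and the
# confidence scores are part of the system's output contract. Remaining
# ties go to the least extreme settings (gamma near 1/d, cost near 1).
svm_grid_search <- function(x, y, hyper, seed) {
  folds <- make_folds(as.character(y), hyper$inner_k, seed)
  grid <- expand.grid(cost = hyper$cost, gamma = hyper$gamma,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in seq_len(hyper$inner_k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr], grid$cost[i],
                     grid$gamma[i], seed = seed)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct / length(y)
  }, numeric(1))
  tied <- which(acc == max(acc))
  if (length(tied) > 1L) {
    conf <- vapply(tied, function(i) {
      tot <- 0
      for (f in seq_len(hyper$inner_k)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) next
        fit <- svm_fit(x[tr, , drop = FALSE], y[tr], grid$cost[i],
                       grid$gamma[i], probability = TRUE, seed = seed)
        pr <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                                  probability = TRUE), "probabilities")
        truth <- as.character(y[!tr])
        keep <- truth %in% colnames(pr)
        tot <- tot + sum(pr[cbind(which(keep), match(truth[keep],
                                                     colnames(pr)))])
      }
      tot / length(y)
    }, numeric(1))
    key <- abs(log2(grid$gamma[tied] * ncol(x))) +
      abs(log2(grid$cost[tied])) / 8
    tied <- tied[order(-conf, key)][1]
  }
  list(cost = grid$cost[tied], gamma = grid$gamma[tied],
       accuracy = max(acc))
}

#' Train one recipe's classifier
#'
#' Builds the recipe's features for every eligible training sequence
#' (sequences lacking a required region are skipped with a warning),
#' scales each feature to \[0,1\], selects RBF hyperparameters by grid
#' search under 3-fold cross-validation, and fits the final multi-class
#' SVM with pairwise-coupled probability estimates. Refitting with the
#' same data and seed reproduces identical predictions.
#'
#' @param train a `labeled_dataset`.
#' @param recipe_id registered recipe id.
#' @param refdbs reference databases built from the same training set.
#' @param scheme a [scoring_scheme()].
#' @param configs see [default_configs()].
#' @param hyper see [default_hyper()].
#' @param seed integer seed.
#' @param features optional precomputed [feature_matrix()] (rows for all
#'   training ids, NA where regions are absent).
#' @param cv_accuracy optional externally computed (leakage-free)
#'   cross-validated accuracy to record; defaults to the grid search's
#'   selection accuracy.
#' @return A `trained_model`.
#' @export
train_model <- function(train, recipe_id, refdbs, scheme = scoring_scheme(),
                        configs = default_configs(), hyper = default_hyper(),
                        seed = 1L, features = NULL, cv_accuracy = NULL) {
  recipe <- get_recipe(recipe_id)
  annotations <- train$annotations
  if (is.null(features)) {
    features <- feature_matrix(train, annotations, refdbs, scheme, configs,
                               self_exclude = TRUE)
  }
  cols <- recipe_columns(recipe, configs)
  x <- features[train$seqs$id, cols, drop = FALSE]
  eligible <- stats::complete.cases(x)
  if (any(!eligible)) {
    warning("recipe ", recipe_id, ": skipped ", sum(!eligible),
            " sequence(s) lacking required region(s)", call. = FALSE)
  }
  x <- x[eligible, , drop = FALSE]
  if (any(!is.finite(x))) {
    bad <- rownames(x)[!apply(is.finite(x), 1, all)][1]
    stop("non-finite feature for sequence ", bad, call. = FALSE)
  }
  y <- factor(train$labels[rownames(x)], levels = gene_classes())
  tab <- table(droplevels(y))
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("degenerate class sizes for recipe ", recipe_id, ": need >=2 ",
         "classes with >=2 members each", call. = FALSE)
  }
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  best <- svm_grid_search(xs, y, hyper, seed)
  fit <- svm_fit(xs, y, best$cost, best$gamma, probability = TRUE,
                 seed = seed)
  structure(list(recipe = recipe, scaler = scaler, fit = fit,
                 class_order = gene_classes(),
                 cv_accuracy = cv_accuracy %||% best$accuracy,
                 cost = best$cost, gamma = best$gamma, seed = seed,
                 n_train = nrow(x)),
            class = "trained_model")
}

# probabilities (in gene_classes order, rows summing to 1) for a scaled
# feature matrix
model_probs <- function(model, xs) {
  pred <- stats::predict(model$fit, xs, probability = TRUE)
  pr <- attr(pred, "probabilities")
  out <- matrix(0, nrow = nrow(xs), ncol = 8L,
                dimnames = list(rownames(xs), gene_classes()))
  out[, colnames(pr)] <- pr
  sweep(out, 1, rowSums(out), "/")
}

#' Leakage-free k-fold cross-validation of one recipe
#'
#' Reference databases are rebuilt inside each fold from that fold's
#' training split only, so held-out sequences never contribute to the
#' similarity databases they are scored against. Fold assignment is
#' stratified by class (with a non-stratified fallback when a class has
#' fewer members than k) and deterministic per seed.
#'
#' @inheritParams train_model
#' @param k number of folds (default 3).
#' @param details also return fold assignments and per-fold reference
#'   database ids (for leakage auditing).
#' @return List with `fold_accuracy` (length k) and `mean_accuracy`; plus
#'   `folds` and `fold_refdb_ids` when `details = TRUE`.
#' @export
cross_validate <- function(train, recipe_id, k = 3L, seed = 1L,
                           scheme = scoring_scheme(),
                           configs = default_configs(),
                           hyper = default_hyper(), details = FALSE) {
  res <- cv_recipes(train, recipe_id, k = k, seed = seed, scheme = scheme,
                    configs = configs, hyper = hyper, details = details)
  out <- list(fold_accuracy = res$fold_accuracy[, recipe_id],
              mean_accuracy = res$mean_accuracy[[recipe_id]])
  if (details) {
    out$folds <- res$folds
    out$fold_refdb_ids <- res$fold_refdb_ids
  }
  out
}

# shared CV engine: one pass over folds computes features once per fold
# and evaluates every requested recipe on them
cv_recipes <- function(train, recipe_ids, k = 3L, seed = 1L,
                       scheme = scoring_scheme(),
                       configs = default_configs(),
                       hyper = default_hyper(), details = FALSE) {
  ids <- train$seqs$id
  folds <- make_folds(as.character(train$labels[ids]), k, seed)
  fold_acc <- matrix(NA_real_, nrow = k, ncol = length(recipe_ids),
                     dimnames = list(NULL, recipe_ids))
  fold_refdb_ids <- list()
  for (f in seq_len(k)) {
    tr_ids <- ids[folds != f]
    te_ids <- ids[folds == f]
    tr <- subset_dataset(train, tr_ids)
    refdbs <- build_reference_databases(tr)
    fold_refdb_ids[[f]] <- unique(unlist(lapply(refdbs, function(db) {
      unlist(lapply(db$per_class, function(ps) ps$id), use.names = FALSE)
    })))
    feat_tr <- feature_matrix(tr, tr$annotations, refdbs, scheme, configs,
                              self_exclude = TRUE)
    te <- subset_dataset(train, te_ids)
    feat_te <- feature_matrix(te, te$annotations, refdbs, scheme, configs,
                              self_exclude = FALSE)
    for (rid in recipe_ids) {
      recipe <- get_recipe(rid)
      cols <- recipe_columns(recipe, configs)
      x_tr <- feat_tr[, cols, drop = FALSE]
      el_tr <- stats::complete.cases(x_tr)
      x_tr <- x_tr[el_tr, , drop = FALSE]
      y_tr <- factor(train$labels[rownames(x_tr)], levels = gene_classes())
      if (length(unique(y_tr)) < 2L) next
      scaler <- fit_scaler(x_tr)
      best <- svm_grid_search(apply_scaler(x_tr, scaler), y_tr, hyper, seed)
      fit <- svm_fit(apply_scaler(x_tr, scaler), y_tr, best$cost, best$gamma,
                     seed = seed)
      x_te <- feat_te[, cols, drop = FALSE]
      el_te <- stats::complete.cases(x_te)
      x_te <- x_te[el_te, , drop = FALSE]
      if (!nrow(x_te)) next
      pred <- stats::predict(fit, apply_scaler(x_te, scaler, clamp = TRUE))
      truth <- as.character(train$labels[rownames(x_te)])
      fold_acc[f, rid] <- mean(as.character(pred) == truth)
    }
  }
  out <- list(fold_accuracy = fold_acc,
              mean_accuracy = colMeans(fold_acc, na.rm = TRUE))
  if (details) {
    out$folds <- stats::setNames(folds, ids)
    out$fold_refdb_ids <- fold_refdb_ids
  }
  out
}

#' Train the full routed classification system
#'
#' Trains all nine registered recipes on a labeled reference set:
#' leakage-free outer cross-validation determines each recipe's recorded
#' CV accuracy (used for routing), then each model is refitted on the
#' full set. Sequences are stage-1 annotated when the dataset carries no
#' annotations.
#'
#' @param train a `labeled_dataset` with every class present.
#' @param scheme a [scoring_scheme()].
#' @param configs see [default_configs()].
#' @param hyper see [default_hyper()].
#' @param k outer CV folds (default 3).
#' @param seed integer seed.
#' @param recipe_ids recipes to train (default: all nine).
#' @param rescan stage-1 annotate the training sequences with the
#'   configured scanner (default TRUE). Training on scanner output keeps
#'   the reference databases consistent with how queries are segmented at
#'   prediction time; set FALSE to trust the dataset's own annotations.
#' @return A `mads_system`: models, reference databases, configuration
#'   and the CV table.
#' @export
mads_train <- function(train, scheme = scoring_scheme(),
                       configs = default_configs(), hyper = default_hyper(),
                       k = 3L, seed = 1L, recipe_ids = NULL, rescan = TRUE) {
  if (is.null(recipe_ids)) {
    recipe_ids <- vapply(registered_recipes(), `[[`, character(1),
                         "recipe_id")
  }
  if (rescan || !length(train$annotations) ||
      !all(train$seqs$id %in% names(train$annotations))) {
    train$annotations <- annotate_domain_set(train$seqs, configs$scan)
  }
  cv <- cv_recipes(train, recipe_ids, k = k, seed = seed, scheme = scheme,
                   configs = configs, hyper = hyper)
  refdbs <- build_reference_databases(train)
  features <- feature_matrix(train, train$annotations, refdbs, scheme,
                             configs, self_exclude = TRUE)
  models <- lapply(recipe_ids, function(rid) {
    train_model(train, rid, refdbs, scheme, configs, hyper, seed = seed,
                features = features,
                cv_accuracy = unname(cv$mean_accuracy[[rid]]))
  })
  names(models) <- recipe_ids
  structure(list(models = models, refdbs = refdbs, scheme = scheme,
                 configs = configs, hyper = hyper, seed = seed,
                 cv_table = data.frame(recipe = recipe_ids,
                                       cv_accuracy =
                                         unname(cv$mean_accuracy[recipe_ids]),
                                       stringsAsFactors = FALSE),
                 train_name = train$name),
            class = "mads_system")
}

#' @export
print.mads_system <- function(x, ...) {
  cat("mads_system trained on '", x$train_name, "' (seed ", x$seed, ")\n",
      sep = "")
  tab <- x$cv_table[order(-x$cv_table$cv_accuracy), ]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s cv_accuracy %.3f\n", tab$recipe[i],
                tab$cv_accuracy[i]))
  }
  invisible(x)
}

#' Route a query to the best feasible model
#'
#' Among models whose required regions are all present in the query's
#' annotation, returns the one with the highest recorded CV accuracy
#' (ties broken by registration order). Rejects non-MIKC queries.
#'
#' @param annotation the query's [domain_annotation()].
#' @param models named list of `trained_model`s in registration order.
#' @return The selected `trained_model`.
#' @export
select_model <- function(annotation, models) {
  if (!annotation$is_mikc) {
    stop("not MIKC-type: no M-domain pattern match", call. = FALSE)
  }
  present <- regions_present(annotation)
  feasible <- Filter(function(m) {
    all(m$recipe$required_regions %in% present)
  }, models)
  if (!length(feasible)) {
    stop("no feasible model for present regions: ",
         paste(present, collapse = ", "), call. = FALSE)
  }
  accs <- vapply(feasible, `[[`, numeric(1), "cv_accuracy")
  feasible[[which.max(accs)]]  # which.max: first max = registration order
}

# predict one sequence with a specific model; enforce_regions = FALSE
# allows forcing the whole-sequence model onto fragments (benchmark mode)
predict_with_model <- function(system, residues, annotation, model,
                               enforce_regions = TRUE) {
  configs <- system$configs
  if (enforce_regions) {
    fv <- build_feature_vector(residues, annotation, model$recipe$recipe_id,
                               system$refdbs, system$scheme, configs,
                               exclude_self_id = NULL)
  } else {
    # forced mode: treat the full (fragment) string as the WHOLE region
    stopifnot(identical(model$recipe$blocks, "sim:WHOLE"))
    v <- region_sim_features(residues, system$refdbs$WHOLE, system$scheme,
                             NULL, configs$evalue_threshold)
    fv <- stats::setNames(as.numeric(v),
                          paste0("sim:WHOLE:", gene_classes()))
  }
  xs <- apply_scaler(matrix(fv, nrow = 1,
                            dimnames = list("q", names(fv))),
                     model$scaler, clamp = TRUE)
  probs <- model_probs(model, xs)[1, ]
  predicted <- gene_classes()[which.max(probs[gene_classes()])]
  list(predicted = predicted, confidence = probs[gene_classes()])
}

#' Classify query sequences
#'
#' Stage 1 annotates each query and rejects non-MIKC sequences; stage 2
#' routes each accepted query to the best feasible model and reports the
#' predicted class with the eight per-class confidence scores
#' (pairwise-coupled SVM probabilities, summing to 1).
#'
#' @param system a [mads_train()] result.
#' @param queries a [protein_set()].
#' @param routing `"auto"` (domain-aware, the default) or `"whole"`
#'   (force the whole-sequence similarity model regardless of domain
#'   content — the comparison mode used in benchmarks).
#' @return Data frame with one row per query: `sequence_id`,
#'   `domain_content`, `model_used`, `predicted`, `rejected`, and the
#'   eight confidence columns (`conf_A` ... `conf_AGL6`).
#' @export
mads_predict <- function(system, queries, routing = c("auto", "whole")) {
  routing <- match.arg(routing)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    id <- queries$id[i]
    residues <- queries$residues[i]
    ann <- annotate_domains(residues, system$configs$scan, id)
    base <- data.frame(sequence_id = id,
                       domain_content = domain_content_key(ann),
                       model_used = NA_character_,
                       predicted = NA_character_, rejected = FALSE,
                       stringsAsFactors = FALSE)
    conf <- stats::setNames(rep(NA_real_, 8L),
                            paste0("conf_", gene_classes()))
    if (!ann$is_mikc) {
      base$rejected <- TRUE
      base$model_used <- "rejected: not MIKC-type"
      return(cbind(base, as.data.frame(as.list(conf))))
    }
    if (routing == "whole") {
      model <- system$models[["WHOLE-sim"]]
      res <- predict_with_model(system, residues, ann, model,
                                enforce_regions = FALSE)
    } else {
      model <- select_model(ann, system$models)
      res <- predict_with_model(system, residues, ann, model)
    }
    base$model_used <- model$recipe$recipe_id
    base$predicted <- res$predicted
    conf[] <- res$confidence
    cbind(base, as.data.frame(as.list(conf)))
  })
  do.call(rbind, rows)
}

#' Accuracy summary of a prediction table
#'
#' Pure arithmetic on a prediction table and its truth labels: per-gene
#' correctness, overall accuracy (also as a percentage rounded to two
#' decimals, the convention of published accuracy tables) and the 8x8
#' confusion matrix. Rejected or unpredicted rows count as incorrect.
#'
#' @param predictions a [mads_predict()] result.
#' @param truth named character vector: sequence id -> true class.
#' @return List with `table` (per-gene rows incl. `correct`),
#'   `n_correct`, `n_total`, `accuracy` (fraction), `accuracy_pct`
#'   (percentage, 2 d.p.), `confusion`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(all(predictions$sequence_id %in% names(truth)))
  tab <- predictions
  tab$true_class <- unname(truth[tab$sequence_id])
  tab$correct <- !is.na(tab$predicted) & tab$predicted == tab$true_class
  n_correct <- sum(tab$correct)
  n_total <- nrow(tab)
  confusion <- table(factor(tab$true_class, levels = gene_classes()),
                     factor(tab$predicted, levels = gene_classes()),
                     dnn = c("true", "predicted"))
  list(table = tab, n_correct = n_correct, n_total = n_total,
       accuracy = n_correct / n_total,
       accuracy_pct = round(100 * n_correct / n_total, 2),
       confusion = confusion)
}

#' Classify and score a labeled dataset
#'
#' @param system a [mads_train()] result.
#' @param labeled a `labeled_dataset`.
#' @param routing see [mads_predict()].
#' @return An [evaluate_predictions()] report.
#' @export
mads_evaluate <- function(system, labeled, routing = "auto") {
  preds <- mads_predict(system, labeled$seqs, routing = routing)
  evaluate_predictions(preds, labeled$labels)
}

#' Render a prediction table in the published two-decimal style
#'
#' @param report an [evaluate_predictions()] report.
#' @return Data frame with gene, true class, predicted class and the
#'   eight confidence scores rounded to two decimals.
#' @export
format_prediction_table <- function(report) {
  tab <- report$table
  out <- data.frame(gene = tab$sequence_id, gene_class = tab$true_class,
                    predicted_class = tab$predicted,
                    stringsAsFactors = FALSE)
  for (cl in gene_classes()) {
    out[[cl]] <- sprintf("%.2f", tab[[paste0("conf_", cl)]])
  }
  out
}
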