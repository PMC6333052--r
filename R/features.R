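#' Build region-restricted reference databases
#'
#' One database per region (`WHOLE`, `M`, `I`, `K`, `C_TERM`), each
#' holding the per-class region subsequences of the training set; the
#' whole-sequence database contains every sequence, domain databases only
#' the sequences whose annotation has that span.
#'
#' @param train a `labeled_dataset` with every class present.
#' @param annotations named list of [domain_annotation()] covering every
#'   training sequence (defaults to the dataset's own annotations).
#' @return Named list of `ref_database` objects: each a list with
#'   `region` and `per_class` (named list of [protein_set()] over
#'   [gene_classes()]).
#' @export
build_reference_databases <- function(train, annotations = train$annotations) {
  if (!nrow(train$seqs)) stop("empty training set", call. = FALSE)
  missing_cls <- setdiff(gene_classes(), train$labels)
  if (length(missing_cls)) {
    stop("training set missing class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  no_ann <- setdiff(train$seqs$id, names(annotations))
  if (length(no_ann)) {
    stop("unannotated training sequence(s): ",
         paste(utils::head(no_ann, 5), collapse = ", "), call. = FALSE)
  }
  out <- lapply(region_tags(), function(region) {
    per_class <- lapply(gene_classes(), function(cls) {
      ids <- train$seqs$id[train$labels[train$seqs$id] == cls]
      subs <- vapply(ids, function(id) {
        i <- match(id, train$seqs$id)
        region_subsequence(train$seqs$residues[i], annotations[[id]], region)
      }, character(1))
      keep <- !is.na(subs)
      protein_set(ids[keep], unname(subs[keep]), normalize = FALSE)
    })
    structure(list(region = region,
                   per_class = stats::setNames(per_class, gene_classes())),
              class = "ref_database")
  })
  stats::setNames(out, region_tags())
}

#' Per-class average-bit-score similarity features
#'
#' Aligns the query (already restricted to the database's region) against
#' every member of every class database; a hit passes when its e-value is
#' below the threshold, and the class feature is the mean bit score of
#' passing hits (0 when none pass). Self-comparison is excluded via
#' `exclude_self_id`, mirroring how reference sequences are encoded
#' against their own class.
#'
#' @param query_region_seq residue string for the database's region.
#' @param db a `ref_database`.
#' @param scheme a [scoring_scheme()].
#' @param exclude_self_id subject id to exclude (or NULL).
#' @param evalue_threshold pass threshold (default 1e-5).
#' @return Numeric length 8 in [gene_classes()] order, with attribute
#'   `evalue_threshold`.
#' @export
encode_class_similarity <- function(query_region_seq, db,
                                    scheme = scoring_scheme(),
                                    exclude_self_id = NULL,
                                    evalue_threshold = 1e-5) {
  stopifnot(nzchar(query_region_seq))
  vals <- vapply(gene_classes(), function(cls) {
    members <- db$per_class[[cls]]
    hits <- search_database(query_region_seq, members, scheme,
                            exclude_ids = exclude_self_id %||% character(0))
    passing <- hits$bit_score[hits$evalue < evalue_threshold]
    if (length(passing)) mean(passing) else 0
  }, numeric(1))
  structure(vals, evalue_threshold = evalue_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BindN input scales: side-chain pKa (non-ionizable side chains neutral at
# 7.0), Kyte-Doolittle hydropathy, average residue mass (Da).
bindn_scales <- function() {
  pka <- c(A = 7, R = 12.48, N = 7, D = 3.65, C = 8.3, Q = 7, E = 4.25,
           G = 7, H = 6.0, I = 7, L = 7, K = 10.53, M = 7, F = 7, P = 7,
           S = 7, T = 7, W = 7, Y = 10.07, V = 7)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  mass <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
            Q = 128.13, E = 129.12, G = 57.05, H = 137.14, I = 113.16,
            L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
            S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)
  lapply(list(pka = pka, hydropathy = kd, mass = mass), function(s) {
    s <- s[AA20]
    (s - min(s)) / (max(s) - min(s))
  })
}

#' Physicochemical encoding of the M domain (BindN-style)
#'
#' Per-position triplet of min-max-normalized side-chain pKa,
#' Kyte-Doolittle hydropathy and residue mass, laid out for positions
#' 0..`m_length - 1` (position-major); positions beyond the sequence are
#' zero-padded and X encodes as the three scale means. Fixed length
#' `3 * m_length` (171 by default).
#'
#' @param m_seq the M-region residue string.
#' @param m_length layout length (default 57).
#' @return Numeric vector of length `3 * m_length`.
#' @export
encode_bindn_block <- function(m_seq, m_length = 57L) {
  if (is.na(m_seq) || !nzchar(m_seq)) stop("empty M-domain sequence", call. = FALSE)
  scales <- bindn_scales()
  means <- vapply(scales, mean, numeric(1))
  chars <- strsplit(m_seq, "", fixed = TRUE)[[1]]
  chars <- chars[seq_len(min(length(chars), m_length))]
  out <- numeric(3L * m_length)
  for (i in seq_along(chars)) {
    trip <- if (chars[i] == "X") means else
      vapply(scales, `[[`, numeric(1), chars[i])
    out[(3L * (i - 1L) + 1L):(3L * i)] <- trip
  }
  out
}

#' Assemble the feature vector of a recipe
#'
#' Computes the recipe's blocks (per-region class-similarity vectors,
#' BindN-style M encoding, COILS K aggregation) from the region-restricted
#' subsequences and concatenates them in registered order.
#'
#' @param seq residue string.
#' @param annotation the sequence's [domain_annotation()].
#' @param recipe_id a registered recipe id (see [registered_recipes()]).
#' @param refdbs output of [build_reference_databases()].
#' @param scheme a [scoring_scheme()].
#' @param configs list with elements `coils` ([coils_config()]),
#'   `evalue_threshold`, `m_length` (see [default_configs()]).
#' @param exclude_self_id id excluded from similarity comparisons.
#' @return Named numeric feature vector; names encode block and index.
#' @export
build_feature_vector <- function(seq, annotation, recipe_id, refdbs,
                                 scheme = scoring_scheme(),
                                 configs = default_configs(),
                                 exclude_self_id = NULL) {
  recipe <- get_recipe(recipe_id)
  present <- regions_present(annotation)
  missing <- setdiff(recipe$required_regions, present)
  if (length(missing)) {
    stop("region unavailable: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(recipe$blocks, function(block) {
    if (startsWith(block, "sim:")) {
      region <- sub("^sim:", "", block)
      qseq <- region_subsequence(seq, annotation, region)
      v <- encode_class_similarity(qseq, refdbs[[region]], scheme,
                                   exclude_self_id,
                                   configs$evalue_threshold)
      stats::setNames(as.numeric(v), paste0(block, ":", gene_classes()))
    } else if (block == "bindn") {
      v <- encode_bindn_block(region_subsequence(seq, annotation, "M"),
                              configs$m_length)
      stats::setNames(v, paste0("bindn:", seq_along(v)))
    } else if (block == "coils") {
      prof <- coils_profile(seq, configs$coils)
      v <- encode_coils_block(prof, annotation$spans$K)
      stats::setNames(v, c("coils:mean", "coils:max", "coils:frac50"))
    } else {
      stop("unknown feature block: ", block, call. = FALSE)
    }
  })
  out <- unlist(blocks, use.names = TRUE)
  if (any(!is.finite(out))) {
    stop("non-finite feature value for sequence ",
         annotation$sequence_id, call. = FALSE)
  }
  out
}

#' Default feature-stage configuration
#'
#' @param coils a [coils_config()].
#' @param evalue_threshold similarity-hit gate (default 1e-5).
#' @param m_length BindN-layout length (default 57).
#' @param scan a [scan_config()] for stage-1 annotation.
#' @return List of configuration objects.
#' @export
default_configs <- function(coils = coils_config(), evalue_threshold = 1e-5,
                            m_length = 57L, scan = NULL) {
  if (is.null(scan)) scan <- scan_config(coils = coils)
  list(coils = coils, evalue_threshold = evalue_threshold,
       m_length = as.integer(m_length), scan = scan)
}

#' Export feature vectors as sparse SVM-format text
#'
#' One line per row: `label index:value ...` with 1-based indices and
#' zero values omitted (the sparse text dialect common SVM trainers read).
#'
#' @param x numeric feature matrix (rows = sequences).
#' @param labels vector of numeric or factor labels, one per row.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_format <- function(x, labels, path) {
  stopifnot(nrow(x) == length(labels))
  lab <- if (is.numeric(labels)) labels else as.integer(factor(labels, levels = gene_classes()))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(c(lab[i], sprintf("%d:%g", nz, x[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
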