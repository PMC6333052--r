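#' Read protein sequences from a FASTA file
#'
#' Parses with seqinr and applies the package normalization contract:
#' ids are the first whitespace-delimited header token, residues are
#' uppercased, ambiguity codes map to X, and any other non-alphabet
#' character raises a format error naming the record index.
#'
#' @param path FASTA file path.
#' @return A [protein_set()] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!length(recs)) stop("FASTA '", path, "' contains no records", call. = FALSE)
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  residues <- vapply(seq_along(recs), function(i) {
    raw <- as.character(recs[[i]])
    if (!length(raw) || !nzchar(gsub("[ \t]", "", raw))) {
      stop("FASTA '", path, "': record ", i, " ('", ids[i],
           "') has an empty sequence", call. = FALSE)
    }
    tryCatch(normalize_residues(raw, ids[i]),
             error = function(e) stop("FASTA '", path, "': record ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("FASTA '", path, "': record ", which(!nzchar(ids) | is.na(ids))[1],
         " has a malformed header", call. = FALSE)
  }
  protein_set(ids, residues, desc, normalize = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param x a [protein_set()].
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  names <- ifelse(nzchar(x$description),
                  paste(x$id, x$description), x$id)
  seqinr::write.fasta(as.list(x$residues), names = names,
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

parse_span_field <- function(field, id) {
  if (is.na(field) || !nzchar(field)) return(list())
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  spans <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([A-Z_]+)\\s*:\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", p))[[1]]
    if (length(m) != 4L) {
      stop("manifest row '", id, "': malformed span '", p,
           "' (expected region:start-end)", call. = FALSE)
    }
    spans[[m[2]]] <- c(as.integer(m[3]), as.integer(m[4]))
  }
  spans
}

#' Load a labeled reference dataset (FASTA + TSV manifest)
#'
#' The manifest is a TSV with header columns `sequence_id`, `class` and an
#' optional `domains` column of semicolon-separated `region:start-end`
#' spans (0-based, half-open). The manifest is the single source of class
#' labels; FASTA headers are never interpreted.
#'
#' @param fasta_path FASTA of reference sequences.
#' @param manifest_path TSV manifest.
#' @param name dataset name.
#' @param require_all_classes error unless every one of the eight classes
#'   appears at least once (default TRUE, the training-set contract).
#' @return A `labeled_dataset`: list with `name`, `seqs` ([protein_set()]),
#'   `labels` (named character, values among [gene_classes()]) and
#'   `annotations` (named list of [domain_annotation()], possibly empty).
#' @export
load_labeled_dataset <- function(fasta_path, manifest_path, name = "dataset",
                                 require_all_classes = TRUE) {
  seqs <- read_fasta(fasta_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sequence_id", "class")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns sequence_id and class", call. = FALSE)
  }
  bad_class <- setdiff(unique(man$class), gene_classes())
  if (length(bad_class)) {
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "),
         "; allowed: ", paste(gene_classes(), collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(man$sequence_id, seqs$id)
  if (length(missing_ids)) {
    stop("manifest id(s) absent from FASTA: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  unjoined <- setdiff(seqs$id, man$sequence_id)
  if (length(unjoined)) {
    message("note: ", length(unjoined),
            " FASTA record(s) not in manifest were dropped: ",
            paste(utils::head(unjoined, 5), collapse = ", "),
            if (length(unjoined) > 5) " ..." else "")
  }
  seqs <- seqs[match(man$sequence_id, seqs$id), , drop = FALSE]
  labels <- stats::setNames(man$class, man$sequence_id)
  annotations <- list()
  if ("domains" %in% names(man)) {
    for (i in seq_len(nrow(man))) {
      spans <- parse_span_field(man$domains[i], man$sequence_id[i])
      if (length(spans)) {
        annotations[[man$sequence_id[i]]] <-
          domain_annotation(man$sequence_id[i], spans,
                            seq_length = nchar(seqs$residues[i]))
      }
    }
  }
  labeled_dataset(name, seqs, labels, annotations,
                  require_all_classes = require_all_classes)
}

#' Construct a labeled dataset in memory
#'
#' @inheritParams load_labeled_dataset
#' @param seqs a [protein_set()].
#' @param labels named character vector mapping every sequence id to a class.
#' @param annotations optional named list of [domain_annotation()].
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(name, seqs, labels, annotations = list(),
                            require_all_classes = TRUE) {
  stopifnot(inherits(seqs, "protein_set"))
  if (!all(seqs$id %in% names(labels))) {
    stop("every sequence needs a class label", call. = FALSE)
  }
  labels <- labels[seqs$id]
  bad <- setdiff(unique(labels), gene_classes())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (require_all_classes && !all(gene_classes() %in% labels)) {
    stop("training set must contain every class; missing: ",
         paste(setdiff(gene_classes(), labels), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, seqs = seqs, labels = labels,
                 annotations = annotations),
            class = "labeled_dataset")
}

#' Per-class sequence counts of a labeled dataset
#'
#' @param dataset a `labeled_dataset`.
#' @return Named integer vector over [gene_classes()].
#' @export
class_counts <- function(dataset) {
  tab <- table(factor(dataset$labels, levels = gene_classes()))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset '", x$name, "': ", nrow(x$seqs), " sequences\n", sep = "")
  cc <- class_counts(x)
  cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  cat("  annotations:", length(x$annotations), "\n")
  invisible(x)
}

#' Subset a labeled dataset by sequence id
#'
#' @param dataset a `labeled_dataset`.
#' @param ids ids to keep, in the given order.
#' @param name name for the subset.
#' @return A `labeled_dataset` (class completeness not enforced).
#' @export
subset_dataset <- function(dataset, ids, name = dataset$name) {
  stopifnot(all(ids %in% dataset$seqs$id))
  seqs <- dataset$seqs[match(ids, dataset$seqs$id), , drop = FALSE]
  class(seqs) <- c("protein_set", "data.frame")
  labeled_dataset(name, seqs, dataset$labels[ids],
                  dataset$annotations[intersect(names(dataset$annotations), ids)],
                  require_all_classes = FALSE)
}

#' Write a labeled dataset as FASTA + TSV manifest
#'
#' @param dataset a `labeled_dataset`.
#' @param fasta_path,manifest_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_dataset <- function(dataset, fasta_path, manifest_path) {
  write_fasta(dataset$seqs, fasta_path)
  dom <- vapply(dataset$seqs$id, function(id) {
    ann <- dataset$annotations[[id]]
    if (is.null(ann) || !length(ann$spans)) return("")
    paste(vapply(names(ann$spans), function(nm) {
      sprintf("%s:%d-%d", nm, ann$spans[[nm]][1], ann$spans[[nm]][2])
    }, character(1)), collapse = ";")
  }, character(1))
  man <- data.frame(sequence_id = dataset$seqs$id,
                    class = unname(dataset$labels[dataset$seqs$id]),
                    domains = unname(dom), stringsAsFactors = FALSE)
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(c(fasta = fasta_path, manifest = manifest_path))
}
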