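#' Read a substitution matrix in NCBI text format
#'
#' Whitespace-separated table with a header row of residue letters and one
#' labelled row per residue; `#` lines are comments (the format written by
#' NCBI's `makematrix` and shipped with BLAST+).
#'
#' @param path matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  header <- toks[[1]]
  rows <- toks[-1]
  mat <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  rownames(mat) <- vapply(rows, `[`, character(1), 1L)
  colnames(mat) <- header
  if (any(is.na(mat))) stop("malformed matrix file: ", path, call. = FALSE)
  mat
}

#' Write a substitution matrix in NCBI text format
#'
#' @param mat integer matrix with residue dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c(" ", colnames(mat)), collapse = " "), con, sep = "\n")
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], mat[i, ]), collapse = " "), con, sep = "\n")
  }
  invisible(path)
}

#' Default scoring scheme (BLOSUM62, affine gaps 11/1)
#'
#' BLOSUM62 over the 20 standard residues, with X scoring 0 against
#' everything; gap of length L costs `gap_open + L * gap_extend` (the
#' BLAST convention). The Karlin-Altschul parameters default to the
#' standard gapped BLOSUM62-11/1 values: lambda = 0.267 nats, K = 0.041.
#'
#' @param matrix substitution matrix (default: BLOSUM62 from Biostrings,
#'   subset to the 20 residues, X row/column set to 0).
#' @param gap_open,gap_extend positive integer gap costs.
#' @param lambda,k_const Karlin-Altschul statistics parameters.
#' @return A `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, k_const = 0.041) {
  if (is.null(matrix)) {
    full <- get_blosum62()
    matrix <- full[AA20, AA20]
    matrix <- cbind(rbind(matrix, X = 0L), X = 0L)
  }
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)),
            isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE)),
            gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            lambda > 0, k_const > 0)
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, k_const = k_const),
            class = "scoring_scheme")
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Convert a raw alignment score to a bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score raw Smith-Waterman score.
#' @param scheme a [scoring_scheme()].
#' @return Bit score (float).
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$k_const)) / log(2)
}

#' Karlin-Altschul expectation for a bit score
#'
#' `E = m * n * 2^(-bits)` with per-pair search space `m * n`.
#'
#' @param bits bit score.
#' @param m,n query and subject lengths (>= 1).
#' @return Expected number of chance alignments at this score.
#' @export
evalue <- function(bits, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  m * n * 2^(-bits)
}

# Vectorized local alignment raw scores of one query against many subjects.
# Smith-Waterman via Biostrings (affine gaps, floor 0). X scores 0 because
# the scheme matrix says so.
sw_raw_scores <- function(query, subjects, scheme) {
  if (!length(subjects)) return(numeric(0))
  stopifnot(nzchar(query), all(nzchar(subjects)))
  all_chars <- unique(strsplit(paste(c(query, subjects), collapse = ""), "")[[1]])
  bad <- setdiff(all_chars, rownames(scheme$matrix))
  if (length(bad)) {
    stop("residue(s) absent from scoring matrix: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  sc <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  pmax(0, round(sc))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman under affine gaps (gap of length L costs
#' `gap_open + L * gap_extend`), with Karlin-Altschul bit score and
#' per-pair e-value (search space `|a| * |b|`). The empty alignment scores
#' 0, so raw scores are never negative.
#'
#' @param a,b residue strings, or single-row [protein_set()]s.
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id ids recorded on the hit.
#' @return An `alignment_hit`: list with `raw_score`, `bit_score`,
#'   `evalue`, `query_id`, `subject_id`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        query_id = NA_character_, subject_id = NA_character_) {
  if (inherits(a, "protein_set")) { query_id <- a$id[1]; a <- a$residues[1] }
  if (inherits(b, "protein_set")) { subject_id <- b$id[1]; b <- b$residues[1] }
  raw <- sw_raw_scores(a, b, scheme)
  bits <- bit_score(raw, scheme)
  structure(list(raw_score = raw, bit_score = bits,
                 evalue = evalue(bits, nchar(a), nchar(b)),
                 query_id = query_id, subject_id = subject_id),
            class = "alignment_hit")
}

#' Align a query against every sequence of a database
#'
#' One hit per non-excluded subject, ordered by descending bit score with
#' ties broken by subject id.
#'
#' @param query residue string.
#' @param db a [protein_set()] (may be empty after exclusion).
#' @param scheme a [scoring_scheme()].
#' @param exclude_ids subject ids to leave out (e.g. the query itself).
#' @param query_id id recorded on the hits.
#' @return Data frame: `query_id`, `subject_id`, `raw_score`, `bit_score`,
#'   `evalue`.
#' @export
search_database <- function(query, db, scheme = scoring_scheme(),
                            exclude_ids = character(0),
                            query_id = NA_character_) {
  keep <- !(db$id %in% exclude_ids)
  db <- db[keep, , drop = FALSE]
  if (!nrow(db)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      evalue = numeric(0)))
  }
  raw <- sw_raw_scores(query, db$residues, scheme)
  bits <- bit_score(raw, scheme)
  out <- data.frame(query_id = query_id, subject_id = db$id,
                    raw_score = raw, bit_score = bits,
                    evalue = evalue(bits, nchar(query), nchar(db$residues)),
                    stringsAsFactors = FALSE)
  out[order(-out$bit_score, out$subject_id), , drop = FALSE]
}

#' Local alignment bit scores via an external BLAST+ backend
#'
#' Optional cross-check backend: runs `makeblastdb` + `blastp` (composition
#' based statistics off, no seg filter) and returns the best-HSP bit score
#' per subject. Requires the BLAST+ binaries on the PATH.
#'
#' @param query residue string.
#' @param db a [protein_set()].
#' @return Data frame `subject_id`, `bit_score` (subjects without a
#'   reported HSP are absent).
#' @export
blast_backend_scores <- function(query, db) {
  if (!nzchar(Sys.which("blastp")) || !nzchar(Sys.which("makeblastdb"))) {
    stop("BLAST+ binaries not found on PATH", call. = FALSE)
  }
  tmp <- tempfile("blastdb")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  dbfa <- file.path(tmp, "db.fasta")
  write_fasta(db, dbfa)
  qfa <- file.path(tmp, "q.fasta")
  writeLines(c(">query", query), qfa)
  system2("makeblastdb", c("-in", dbfa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastp",
                 c("-query", qfa, "-db", dbfa, "-outfmt",
                   shQuote("6 sseqid bitscore"),
                   "-comp_based_stats", "0", "-seg", "no", "-evalue", "1000",
                   "-max_hsps", "1"),
                 stdout = TRUE, stderr = FALSE)
  if (!length(out)) {
    return(data.frame(subject_id = character(0), bit_score = numeric(0)))
  }
  parts <- strsplit(out, "\t")
  df <- data.frame(subject_id = vapply(parts, `[`, character(1), 1L),
                   bit_score = as.numeric(vapply(parts, `[`, character(1), 2L)),
                   stringsAsFactors = FALSE)
  df[!duplicated(df$subject_id), , drop = FALSE]
}
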