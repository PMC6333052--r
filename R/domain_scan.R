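#' Stage-1 scan configuration
#'
#' @param m_pattern M-domain detection pattern (a `prosite_pattern` or
#'   PROSITE string); default [default_m_pattern()].
#' @param m_length M-domain length in residues; the first pattern match is
#'   extended to this many residues (default 57, truncated at the sequence
#'   end).
#' @param min_i_length minimum M-to-K gap reported as an I domain.
#' @param k_detect minimum coiled-coil probability of the best K window.
#' @param k_boundary_ratio K-span boundaries keep window placements whose
#'   score is at least this fraction of the best placement's score.
#' @param k_polish_logprop residue-level boundary polish: span ends are
#'   trimmed while the outermost four residues' weighted mean
#'   log-propensity (under the best heptad frame) falls below this value.
#' @param coils a [coils_config()].
#' @return A `scan_config`.
#' @export
scan_config <- function(m_pattern = default_m_pattern(), m_length = 57L,
                        min_i_length = 5L, k_detect = 0.5,
                        k_boundary_ratio = 0.9, k_polish_logprop = 0.25,
                        coils = coils_config()) {
  if (is.character(m_pattern)) m_pattern <- parse_prosite(m_pattern)
  stopifnot(inherits(m_pattern, "prosite_pattern"), m_length >= 1,
            min_i_length >= 1, k_detect > 0, k_detect < 1,
            k_boundary_ratio > 0, k_boundary_ratio <= 1)
  structure(list(m_pattern = m_pattern, m_length = as.integer(m_length),
                 min_i_length = as.integer(min_i_length),
                 k_detect = k_detect, k_boundary_ratio = k_boundary_ratio,
                 k_polish_logprop = k_polish_logprop, coils = coils),
            class = "scan_config")
}

# K span via window-placement scores downstream of the M domain: take the
# largest configured width that fits, keep the contiguous run of
# placements around the best one whose score stays within
# k_boundary_ratio of the best, and require the best placement to reach
# coiled-coil probability k_detect. Returns c(start, end) relative to the
# downstream offset, or NULL.
detect_k_span <- function(residues, offset, config) {
  down <- substring(residues, offset + 1L)
  n <- nchar(down)
  widths <- config$coils$window_widths
  widths <- widths[widths <= n]
  if (!length(widths)) return(NULL)
  w <- max(widths)
  sc <- coils_window_scores(down, config$coils, w)
  i_best <- which.max(sc)
  g <- config$coils$gauss[config$coils$gauss$width == w, ]
  lcc <- stats::dnorm(sc[i_best], g$cc_mean, g$cc_sd, log = TRUE)
  lgl <- stats::dnorm(sc[i_best], g$glob_mean, g$glob_sd, log = TRUE)
  p_best <- 1 / (1 + exp(lgl - lcc))
  if (p_best < config$k_detect) return(NULL)
  cutoff <- sc[i_best] * config$k_boundary_ratio
  lo <- i_best
  while (lo > 1L && sc[lo - 1L] >= cutoff) lo <- lo - 1L
  hi <- i_best
  while (hi < length(sc) && sc[hi + 1L] >= cutoff) hi <- hi + 1L
  span <- polish_k_span(down, lo, hi - 1L + w, config, min_len = w)
  c(offset + span[1], offset + span[2] + 1L)
}

# residue-level boundary polish: under the best global heptad frame for
# the candidate span, trim each end while the outermost `probe` residues
# average below the configured weighted log-propensity. Coordinates are
# 1-based inclusive within `down`; returns 0-based inclusive-start /
# inclusive-end pair (start, end-1) shifted back by the caller.
polish_k_span <- function(down, lo, hi, config, min_len, probe = 4L) {
  chars <- strsplit(down, "", fixed = TRUE)[[1]]
  wts <- unname(config$position_weights %||% config$coils$position_weights)
  j0 <- seq_along(chars) - 1L
  frame_avg <- function(t, a, b) {
    ph <- (j0[a:b] + t) %% 7L
    w <- wts[ph + 1L]
    sum(w * coils_log_prop(chars[a:b], ph, config$coils$propensity)) / sum(w)
  }
  t_best <- which.max(vapply(0:6, frame_avg, numeric(1), a = lo, b = hi)) - 1L
  outer_avg <- function(a, b) frame_avg(t_best, a, b)
  while (hi - lo + 1L > min_len &&
         outer_avg(lo, min(lo + probe - 1L, hi)) < config$k_polish_logprop) {
    lo <- lo + 1L
  }
  while (hi - lo + 1L > min_len &&
         outer_avg(max(hi - probe + 1L, lo), hi) < config$k_polish_logprop) {
    hi <- hi - 1L
  }
  c(lo - 1L, hi - 1L)
}

#' Annotate the MIKC domain architecture of a sequence
#'
#' Stage-1 domain judgement: the M span is the first (leftmost) match of
#' the configured PROSITE pattern, extended to `m_length` residues; when
#' no M match exists the sequence is not MIKC-type and no spans are
#' reported. The K span is the best coiled-coil window region downstream
#' of M (see [scan_config()]); I is the M-to-K gap when long enough;
#' C_TERM is everything after K.
#'
#' @param seq residue string, or a single-row [protein_set()].
#' @param config a [scan_config()].
#' @param sequence_id id recorded on the annotation.
#' @return A [domain_annotation()].
#' @export
annotate_domains <- function(seq, config = scan_config(),
                             sequence_id = NA_character_) {
  if (inherits(seq, "protein_set")) {
    sequence_id <- seq$id[1]
    seq <- seq$residues[1]
  }
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  n <- nchar(seq)
  hits <- match_pattern(config$m_pattern, seq)
  if (!nrow(hits)) {
    return(domain_annotation(sequence_id, list(), seq_length = n))
  }
  m_start <- hits$start[1]
  m_end <- min(m_start + config$m_length, n)
  spans <- list(M = c(m_start, m_end))
  if (m_end < n) {
    k <- detect_k_span(seq, m_end, config)
    if (!is.null(k)) {
      spans$K <- k
      if (k[1] - m_end >= config$min_i_length) spans$I <- c(m_end, k[1])
      if (k[2] < n) spans$C_TERM <- c(k[2], n)
    }
  }
  domain_annotation(sequence_id, spans, seq_length = n)
}

#' Annotate every sequence of a protein set
#'
#' @param seqs a [protein_set()].
#' @param config a [scan_config()].
#' @return Named list of [domain_annotation()] keyed by sequence id.
#' @export
annotate_domain_set <- function(seqs, config = scan_config()) {
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    annotate_domains(seqs$residues[i], config, seqs$id[i])
  })
  stats::setNames(out, seqs$id)
}

#' Canonical domain-content key of an annotation
#'
#' Concatenation of the present region letters in M, I, K, C order (the
#' key the filtration/routing stage screens on); empty string when no
#' span is present.
#'
#' @param annotation a [domain_annotation()].
#' @return Character scalar such as `"MIKC"`, `"M"`, `"KC"`.
#' @export
domain_content_key <- function(annotation) {
  letter <- c(M = "M", I = "I", K = "K", C_TERM = "C")
  tags <- region_tags(include_whole = FALSE)
  paste(letter[tags[tags %in% names(annotation$spans)]], collapse = "")
}

#' Write domain annotations as TSV
#'
#' Columns: `sequence_id`, `region`, `start`, `end` (0-based half-open).
#'
#' @param annotations named list of [domain_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (!length(a$spans)) return(NULL)
    data.frame(sequence_id = a$sequence_id,
               region = names(a$spans),
               start = vapply(a$spans, `[`, integer(1), 1L),
               end = vapply(a$spans, `[`, integer(1), 2L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(sequence_id = character(0), region = character(0),
                       start = integer(0), end = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
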