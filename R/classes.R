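#' The eight gene classes of the extended ABCDE model
#'
#' Fixed-order class labels used for every vector layout, probability table
#' and argmax tie-break in the package: A, B12, B34, BPI, C, D, E, AGL6.
#' The order is part of the package contract and must never be permuted.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' gene_classes()
gene_classes <- function() {
  c("A", "B12", "B34", "BPI", "C", "D", "E", "AGL6")
}

#' Region tags of the MIKC domain architecture
#'
#' `WHOLE` denotes the full-length sequence; `M`, `I`, `K` are the MADS,
#' intervening and keratin-like domains; `C_TERM` is the C-terminal domain
#' (named to avoid collision with the C gene class).
#'
#' @param include_whole include the `WHOLE` pseudo-region (default TRUE).
#' @return Character vector of region tags in N-to-C order.
#' @export
region_tags <- function(include_whole = TRUE) {
  tags <- c("M", "I", "K", "C_TERM")
  if (include_whole) c("WHOLE", tags) else tags
}

# Standard amino-acid alphabet (20 letters) plus the ambiguity letter X.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Normalize a raw amino-acid string
#'
#' Uppercases, maps the ambiguity codes B, Z, U, J, O and the stop symbol
#' `*` to X (with a warning), and rejects any remaining character outside
#' the 20-letter alphabet plus X.
#'
#' @param residues character scalar of residues.
#' @param id sequence id used in error messages.
#' @return Normalized residue string.
#' @export
normalize_residues <- function(residues, id = "<unnamed>") {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[ \t\r\n]", "", residues))
  if (!nzchar(res)) {
    stop("sequence '", id, "': empty residue string", call. = FALSE)
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  amb <- chars %in% c("B", "Z", "U", "J", "O", "*")
  if (any(amb)) {
    warning("sequence '", id, "': mapped ", sum(amb),
            " non-standard residue(s) (B/Z/U/J/O/*) to X", call. = FALSE)
    chars[amb] <- "X"
  }
  bad <- !(chars %in% c(AA20, "X"))
  if (any(bad)) {
    stop("sequence '", id, "': invalid residue character(s): ",
         paste(unique(chars[bad]), collapse = " "), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a set of protein sequences
#'
#' The package represents a sequence set as a data.frame with columns
#' `id`, `residues`, `description`; ids must be unique.
#'
#' @param id character vector of unique ids.
#' @param residues character vector of residue strings (normalized).
#' @param description optional character vector of free-text descriptions.
#' @param normalize run [normalize_residues()] on each entry (default TRUE).
#' @return A `protein_set` data.frame.
#' @export
protein_set <- function(id, residues, description = "", normalize = TRUE) {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (normalize) {
    residues <- vapply(seq_along(residues),
                       function(i) normalize_residues(residues[i], id[i]),
                       character(1))
  }
  out <- data.frame(id = as.character(id),
                    residues = as.character(residues),
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", class(out))
  out
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "sequence(s)\n")
  n <- min(6L, nrow(x))
  for (i in seq_len(n)) {
    r <- x$residues[i]
    cat(sprintf("  %-20s %5d aa  %s%s\n", x$id[i], nchar(r),
                substr(r, 1, 30), if (nchar(r) > 30) "..." else ""))
  }
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Construct a domain annotation
#'
#' Spans are 0-based half-open `[start, end)` intervals, must lie within
#' the sequence, be mutually non-overlapping and ordered M < I < K < C_TERM.
#' `is_mikc` is TRUE exactly when an M span is present.
#'
#' @param sequence_id sequence identifier.
#' @param spans named list of `c(start, end)` integer pairs; names among
#'   `M`, `I`, `K`, `C_TERM`.
#' @param seq_length total sequence length, used for bounds checking.
#' @return A `domain_annotation` object.
#' @export
domain_annotation <- function(sequence_id, spans = list(), seq_length = NULL) {
  order4 <- region_tags(include_whole = FALSE)
  if (length(spans)) {
    bad <- setdiff(names(spans), order4)
    if (length(bad)) stop("unknown region tag(s): ", paste(bad, collapse = ", "))
    spans <- spans[order4[order4 %in% names(spans)]]
    for (nm in names(spans)) {
      sp <- spans[[nm]]
      stopifnot(length(sp) == 2L)
      sp <- as.integer(sp)
      if (sp[1] < 0L || sp[2] <= sp[1]) {
        stop("region ", nm, ": invalid span [", sp[1], ",", sp[2], ")")
      }
      if (!is.null(seq_length) && sp[2] > seq_length) {
        stop("region ", nm, ": span end ", sp[2],
             " exceeds sequence length ", seq_length)
      }
      spans[[nm]] <- sp
    }
    ends <- vapply(spans, `[`, integer(1), 2L)
    starts <- vapply(spans, `[`, integer(1), 1L)
    if (length(spans) > 1L && any(starts[-1L] < ends[-length(ends)])) {
      stop("domain spans overlap or are out of M<I<K<C_TERM order")
    }
  }
  structure(list(sequence_id = sequence_id,
                 spans = spans,
                 is_mikc = "M" %in% names(spans)),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("domain_annotation for", x$sequence_id,
      if (x$is_mikc) "(MIKC-type)" else "(not MIKC-type)", "\n")
  for (nm in names(x$spans)) {
    cat(sprintf("  %-6s [%d, %d)\n", nm, x$spans[[nm]][1], x$spans[[nm]][2]))
  }
  invisible(x)
}

#' Extract a region subsequence
#'
#' @param residues residue string.
#' @param annotation a [domain_annotation()].
#' @param region a region tag; `WHOLE` returns the full string.
#' @return Residue substring, or `NA_character_` when the region is absent.
#' @export
region_subsequence <- function(residues, annotation, region) {
  if (region == "WHOLE") return(residues)
  sp <- annotation$spans[[region]]
  if (is.null(sp)) return(NA_character_)
  substr(residues, sp[1] + 1L, sp[2])
}

#' Regions present in an annotation
#'
#' `WHOLE` is reported as present only when all four domains are present,
#' so that whole-sequence models are routed only to architecturally
#' complete MIKC inputs.
#'
#' @param annotation a [domain_annotation()].
#' @return Character vector of available region tags.
#' @export
regions_present <- function(annotation) {
  tags <- names(annotation$spans)
  if (all(region_tags(include_whole = FALSE) %in% tags)) c("WHOLE", tags) else tags
}
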