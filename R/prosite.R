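#' Parse a PROSITE pattern
#'
#' Supported grammar: elements separated by `-`; an element is a single
#' residue letter, `[..]` (any of), `{..}` (none of) or `x` (any residue);
#' an optional repeat `(n)` or `(n,m)` follows an element; `<` anchors the
#' pattern at the sequence start, `>` at the end; a trailing `.` is
#' ignored. Repeats default to `(1,1)`.
#'
#' @param pattern_string pattern in PROSITE syntax.
#' @return A `prosite_pattern`: list with `raw`, `elements` (each a list
#'   with `kind` = "set"/"any", `set` = allowed residues, `min`, `max`),
#'   `anchored_start`, `anchored_end`.
#' @export
parse_prosite <- function(pattern_string) {
  stopifnot(is.character(pattern_string), length(pattern_string) == 1L)
  s <- gsub("[ \t]", "", pattern_string)
  raw <- s
  s <- sub("\\.$", "", s)
  anchored_start <- startsWith(s, "<")
  if (anchored_start) s <- substring(s, 2L)
  anchored_end <- endsWith(s, ">")
  if (anchored_end) s <- substring(s, 1L, nchar(s) - 1L)
  if (!nzchar(s)) stop("empty PROSITE pattern", call. = FALSE)

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  elements <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    pos0 <- i
    if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      members <- character(0)
      while (j <= n && chars[j] != close) {
        if (chars[j] == "-") {
          stop("PROSITE parse error at position ", pos0,
               ": unbalanced '", ch, "'", call. = FALSE)
        }
        if (!(chars[j] %in% c(AA20, "X"))) {
          stop("PROSITE parse error at position ", j, ": invalid residue '",
               chars[j], "' inside ", ch, close, call. = FALSE)
        }
        members <- c(members, chars[j])
        j <- j + 1L
      }
      if (j > n) stop("PROSITE parse error at position ", pos0,
                      ": unbalanced '", ch, "'", call. = FALSE)
      if (!length(members)) stop("PROSITE parse error at position ", pos0,
                                 ": empty residue class", call. = FALSE)
      members <- unique(members)
      set <- if (ch == "[") members else setdiff(AA20, members)
      if (!length(set)) stop("PROSITE parse error at position ", pos0,
                             ": residue class excludes every residue", call. = FALSE)
      el <- list(kind = "set", set = set, negated = (ch == "{"),
                 members = members)
      i <- j + 1L
    } else if (ch == "x" || ch == "X") {
      el <- list(kind = "any", set = NULL, negated = FALSE, members = NULL)
      i <- i + 1L
    } else if (ch %in% AA20) {
      el <- list(kind = "set", set = ch, negated = FALSE, members = ch)
      i <- i + 1L
    } else {
      stop("PROSITE parse error at position ", i, ": unexpected '", ch, "'",
           call. = FALSE)
    }
    el$min <- 1L; el$max <- 1L
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("PROSITE parse error at position ", i,
                      ": unbalanced '('", call. = FALSE)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(inner, regexec("^([0-9]+)(,([0-9]+))?$", inner))[[1]]
      if (!length(m)) stop("PROSITE parse error at position ", i,
                           ": malformed repeat '(", inner, ")'", call. = FALSE)
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      if (hi < lo) stop("PROSITE parse error at position ", i,
                        ": repeat range (", lo, ",", hi, ") has n>m", call. = FALSE)
      el$min <- lo; el$max <- hi
      i <- j + 1L
    }
    elements[[length(elements) + 1L]] <- el
  }
  if (!length(elements)) stop("empty PROSITE pattern", call. = FALSE)
  structure(list(raw = raw, elements = elements,
                 anchored_start = anchored_start, anchored_end = anchored_end),
            class = "prosite_pattern")
}

#' Render a parsed PROSITE pattern back to syntax
#'
#' `parse_prosite(render_prosite(p))` reproduces `p` for normalized
#' patterns.
#'
#' @param pattern a `prosite_pattern`.
#' @return Pattern string (with trailing `.`).
#' @export
render_prosite <- function(pattern) {
  parts <- vapply(pattern$elements, function(el) {
    core <- if (el$kind == "any") {
      "x"
    } else if (el$negated) {
      paste0("{", paste(el$members, collapse = ""), "}")
    } else if (length(el$members) > 1L) {
      paste0("[", paste(el$members, collapse = ""), "]")
    } else el$members
    if (el$min == 1L && el$max == 1L) core
    else if (el$min == el$max) paste0(core, "(", el$min, ")")
    else paste0(core, "(", el$min, ",", el$max, ")")
  }, character(1))
  paste0(if (pattern$anchored_start) "<" else "",
         paste(parts, collapse = "-"),
         if (pattern$anchored_end) ">" else "", ".")
}

# Can residue `ch` satisfy element `el`? X in the sequence matches only the
# wildcard element `x` (the package default policy).
element_matches <- function(el, ch) {
  if (el$kind == "any") return(TRUE)
  if (ch == "X") return(FALSE)
  ch %in% el$set
}

# Greedy backtracking match of elements[k..] at 0-based position pos.
# Returns the 0-based end (exclusive) of the match, or -1L.
match_from <- function(chars, pos, elements, k, anchored_end) {
  if (k > length(elements)) {
    if (anchored_end && pos != length(chars)) return(-1L)
    return(pos)
  }
  el <- elements[[k]]
  # count how many residues from pos satisfy this element, up to max
  avail <- 0L
  while (avail < el$max && pos + avail < length(chars) &&
         element_matches(el, chars[pos + avail + 1L])) {
    avail <- avail + 1L
  }
  if (avail < el$min) return(-1L)
  for (take in seq(avail, el$min)) {  # greedy: longest first
    res <- match_from(chars, pos + take, elements, k + 1L, anchored_end)
    if (res >= 0L) return(res)
  }
  -1L
}

#' Match a PROSITE pattern against a sequence
#'
#' Scans left to right and reports all maximal-leftmost, non-overlapping
#' matches; repeats are greedy (with backtracking), matching the semantics
#' of a greedy regular-expression engine. An X in the sequence matches only
#' the wildcard element `x`.
#'
#' @param pattern a `prosite_pattern` (or a pattern string, parsed on the
#'   fly).
#' @param residues residue string (normalized).
#' @return Data frame with 0-based half-open columns `start`, `end`; zero
#'   rows when there is no match.
#' @export
match_pattern <- function(pattern, residues) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  repeat {
    if (pos > n) break
    e <- match_from(chars, pos, pattern$elements, 1L, pattern$anchored_end)
    if (e >= 0L) {
      starts <- c(starts, pos); ends <- c(ends, e)
      pos <- if (e > pos) e else pos + 1L
    } else {
      pos <- pos + 1L
    }
    if (pattern$anchored_start) break
  }
  data.frame(start = starts, end = ends)
}

#' Read a PROSITE pattern file
#'
#' One pattern per line; `#` starts a comment; blank lines ignored. The
#' first pattern is the default M-domain pattern.
#'
#' @param path pattern file.
#' @return List of `prosite_pattern` objects.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no patterns in ", path, call. = FALSE)
  lapply(lines, parse_prosite)
}

#' The package's default M-domain pattern
#'
#' A PROSITE-syntax pattern for the conserved core of the plant MADS
#' DNA-binding helix (the KRIEN...KRR stretch shared by MIKC-type
#' proteins). Shipped as editable config in
#' `system.file("extdata", "mads_m_pattern.txt", package = "madsbox")`.
#'
#' @return A `prosite_pattern`.
#' @export
default_m_pattern <- function() {
  path <- system.file("extdata", "mads_m_pattern.txt", package = "madsbox")
  read_pattern_file(path)[[1]]
}
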