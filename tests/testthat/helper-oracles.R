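# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive and separate from the package's implementations.

# ---- Smith-Waterman oracle: exhaustive path enumeration with memoisation.
# State machine over (i, j, last op); gap of length L costs open + L * ext,
# alignments may start and end anywhere, the empty alignment scores 0.
sw_oracle <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca); nb <- length(cb)
  memo <- array(NA_real_, dim = c(na + 1L, nb + 1L, 3L))
  # last: 1 = match/start, 2 = gap in a (consume b), 3 = gap in b (consume a)
  rec <- function(i, j, last) {
    if (!is.na(memo[i + 1L, j + 1L, last])) return(memo[i + 1L, j + 1L, last])
    best <- 0  # stop here
    if (i < na && j < nb) {
      best <- max(best, mat[ca[i + 1L], cb[j + 1L]] + rec(i + 1L, j + 1L, 1L))
    }
    if (j < nb) {
      cost <- ext + if (last == 2L) 0 else open
      best <- max(best, -cost + rec(i, j + 1L, 2L))
    }
    if (i < na) {
      cost <- ext + if (last == 3L) 0 else open
      best <- max(best, -cost + rec(i + 1L, j, 3L))
    }
    memo[i + 1L, j + 1L, last] <<- best
    best
  }
  best <- 0
  for (i in 0:(na - 1L)) {
    for (j in 0:(nb - 1L)) {
      # any local alignment must begin with an aligned pair
      best <- max(best, mat[ca[i + 1L], cb[j + 1L]] + rec(i + 1L, j + 1L, 1L))
    }
  }
  best
}

random_protein <- function(n, alphabet = madsbox:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- COILS oracle: naive loop over widths, window placements, frames and
# positions, all in log space.
coils_oracle <- function(residues, config) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  wts <- config$position_weights
  if (n < min(config$window_widths)) return(rep(0, n))
  probs <- rep(0, n)
  for (w in config$window_widths) {
    if (n < w) next
    res_score <- rep(-Inf, n)
    for (start in 1:(n - w + 1L)) {
      win_best <- -Inf
      for (f in 0:6) {
        s <- 0; tw <- 0
        for (k in 0:(w - 1L)) {
          ph <- (k + f) %% 7L
          wgt <- wts[[letters[ph + 1L]]]
          s <- s + wgt * log(config$propensity[chars[start + k], ph + 1L])
          tw <- tw + wgt
        }
        win_best <- max(win_best, s / tw)
      }
      for (k in 0:(w - 1L)) {
        res_score[start + k] <- max(res_score[start + k], win_best)
      }
    }
    g <- config$gauss[config$gauss$width == w, ]
    sc <- exp(res_score)
    lcc <- stats::dnorm(sc, g$cc_mean, g$cc_sd, log = TRUE)
    lgl <- stats::dnorm(sc, g$glob_mean, g$glob_sd, log = TRUE)
    probs <- pmax(probs, 1 / (1 + exp(lgl - lcc)))
  }
  probs
}

# ---- PROSITE regex-translation oracle
prosite_to_regex <- function(pattern) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  parts <- vapply(pattern$elements, function(el) {
    core <- if (el$kind == "any") "."
    else if (el$negated) paste0("[^", paste(el$members, collapse = ""), "]")
    else if (length(el$set) > 1L) paste0("[", paste(el$set, collapse = ""), "]")
    else el$set
    rep_str <- if (el$min == 1L && el$max == 1L) ""
    else if (el$min == el$max) sprintf("{%d}", el$min)
    else sprintf("{%d,%d}", el$min, el$max)
    paste0(core, rep_str)
  }, character(1))
  paste0(if (pattern$anchored_start) "^" else "",
         paste(parts, collapse = ""),
         if (pattern$anchored_end) "$" else "")
}

regex_match_spans <- function(pattern, residues) {
  rx <- prosite_to_regex(pattern)
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# random PROSITE pattern over the 20-letter alphabet (no X in sequences it
# is tested against; repeats kept >= 1)
random_pattern <- function() {
  n_el <- sample(2:6, 1)
  els <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("single", "set", "negset", "any"), 1,
                   prob = c(.4, .25, .15, .2))
    core <- switch(kind,
      single = sample(madsbox:::AA20, 1),
      set = paste0("[", paste(sample(madsbox:::AA20, sample(2:3, 1)),
                              collapse = ""), "]"),
      negset = paste0("{", paste(sample(madsbox:::AA20, sample(1:2, 1)),
                                 collapse = ""), "}"),
      any = "x")
    rep_kind <- sample(c("none", "fixed", "range"), 1, prob = c(.6, .2, .2))
    paste0(core, switch(rep_kind,
      none = "",
      fixed = sprintf("(%d)", sample(1:3, 1)),
      range = {
        lo <- sample(1:2, 1)
        sprintf("(%d,%d)", lo, lo + sample(1:2, 1))
      }))
  }, character(1))
  anchor_s <- stats::runif(1) < 0.1
  anchor_e <- stats::runif(1) < 0.1
  paste0(if (anchor_s) "<" else "", paste(els, collapse = "-"),
         if (anchor_e) ">" else "", ".")
}
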