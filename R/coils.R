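#' Coiled-coil scoring configuration
#'
#' Bundles the residue-by-heptad-position propensity table, the heptad
#' position weights (a,d = 2.5; b,c,e,f,g = 1.0), the sliding-window
#' widths (14, 21, 28 by default, combined by per-residue maximum) and the
#' per-width Gaussian parameters of the coiled-coil and globular score
#' distributions used to turn a window score into a probability.
#'
#' The default tables ship as plain-text files under
#' `system.file("extdata", package = "madsbox")`; the propensity table is
#' a package-authored surrogate (see the methods vignette) encoding the
#' canonical a/d-hydrophobic heptad preference, and the Gaussian
#' parameters were calibrated once against that table.
#'
#' @param propensity_path TSV: column `residue` then columns `a`..`g`.
#' @param gauss_path TSV: columns `width`, `cc_mean`, `cc_sd`, `glob_mean`,
#'   `glob_sd`.
#' @param position_weights named numeric over `a`..`g`.
#' @param window_widths increasing integer vector.
#' @param matrix_name label recorded on the config.
#' @return A `coils_config`.
#' @export
coils_config <- function(propensity_path = NULL, gauss_path = NULL,
                         position_weights = c(a = 2.5, b = 1, c = 1, d = 2.5,
                                              e = 1, f = 1, g = 1),
                         window_widths = c(14L, 21L, 28L),
                         matrix_name = "MTIDK-like (package surrogate)") {
  if (is.null(propensity_path)) {
    propensity_path <- system.file("extdata", "coils_propensity_synthetic.tsv",
                                   package = "madsbox")
  }
  if (is.null(gauss_path)) {
    gauss_path <- system.file("extdata", "coils_gauss_synthetic.tsv",
                              package = "madsbox")
  }
  prop_df <- utils::read.delim(propensity_path, stringsAsFactors = FALSE)
  prop <- as.matrix(prop_df[, letters[1:7]])
  rownames(prop) <- prop_df$residue
  if (any(prop <= 0)) stop("propensities must be positive", call. = FALSE)
  gauss <- utils::read.delim(gauss_path, stringsAsFactors = FALSE)
  stopifnot(all(c("width", "cc_mean", "cc_sd", "glob_mean", "glob_sd")
                %in% names(gauss)))
  window_widths <- sort(as.integer(window_widths))
  if (!all(window_widths %in% gauss$width)) {
    stop("gauss_params missing for width(s): ",
         paste(setdiff(window_widths, gauss$width), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(position_weights > 0),
            identical(sort(names(position_weights)), letters[1:7]))
  structure(list(propensity = prop, gauss = gauss,
                 position_weights = position_weights[letters[1:7]],
                 window_widths = window_widths,
                 matrix_name = matrix_name),
            class = "coils_config")
}

# Weighted log-score of every window placement of width w: best heptad
# frame per start, computed over the 7 global phase shifts via cumsums.
# lp/wv are 7 x n matrices of weighted log propensities and weights.
window_start_log_scores <- function(lp, wv, w, n) {
  nstart <- n - w + 1L
  best <- rep(-Inf, nstart)
  for (t in 0:6) {
    cs <- c(0, cumsum(lp[t + 1L, ]))
    cw <- c(0, cumsum(wv[t + 1L, ]))
    sc <- (cs[(w + 1L):(n + 1L)] - cs[1:nstart]) /
          (cw[(w + 1L):(n + 1L)] - cw[1:nstart])
    best <- pmax(best, sc)
  }
  best
}

# shared setup: per-shift weighted log propensity and weight matrices
coils_shift_matrices <- function(chars, config) {
  n <- length(chars)
  wts <- unname(config$position_weights)
  lp <- matrix(0, nrow = 7L, ncol = n)
  wv <- matrix(0, nrow = 7L, ncol = n)
  j0 <- seq_len(n) - 1L
  for (t in 0:6) {
    ph <- (j0 + t) %% 7L
    lp[t + 1L, ] <- wts[ph + 1L] * coils_log_prop(chars, ph, config$propensity)
    wv[t + 1L, ] <- wts[ph + 1L]
  }
  list(lp = lp, wv = wv)
}

#' Window-placement scores of a sequence at one width
#'
#' Best-frame weighted geometric-mean score of every window placement;
#' used by stage-1 K-span boundary detection and exposed for inspection.
#'
#' @param residues residue string.
#' @param config a [coils_config()].
#' @param width window width (must not exceed the sequence length).
#' @return Numeric vector of length `nchar(residues) - width + 1`.
#' @export
coils_window_scores <- function(residues, config = coils_config(), width) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < width) stop("sequence shorter than window width", call. = FALSE)
  m <- coils_shift_matrices(chars, config)
  exp(window_start_log_scores(m$lp, m$wv, width, n))
}

# log-propensity of residue ch at heptad phase p (0-based, 0 == 'a')
coils_log_prop <- function(chars, phases, prop) {
  idx <- cbind(match(chars, rownames(prop)), phases + 1L)
  if (anyNA(idx[, 1])) {
    stop("residue(s) absent from propensity table: ",
         paste(unique(chars[is.na(idx[, 1])]), collapse = " "), call. = FALSE)
  }
  log(prop[idx])
}

#' Per-residue coiled-coil probability profile
#'
#' For every window width, window placement and each of the 7 heptad frame
#' offsets, the window score is the weighted geometric mean of the
#' per-residue propensities (exponents = position weights, normalized by
#' the total weight), maximized over frames; each residue receives the
#' best score among windows covering it; the score maps to a probability
#' via the two-Gaussian likelihood ratio
#' `P = G_cc(s) / (G_cc(s) + G_glob(s))`, and the final per-residue
#' probability is the maximum over widths.
#'
#' @param residues residue string.
#' @param config a [coils_config()].
#' @return A `coils_profile`: list with `probabilities` (length =
#'   sequence length, in \[0,1\]), `per_window_scores` (named list of
#'   per-residue best window scores by width), `too_short` flag.
#' @export
coils_profile <- function(residues, config = coils_config()) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  wts <- unname(config$position_weights)
  if (n < min(config$window_widths)) {
    return(structure(list(probabilities = rep(0, n),
                          per_window_scores =
                            stats::setNames(rep(list(rep(0, n)),
                                                length(config$window_widths)),
                                            config$window_widths),
                          too_short = TRUE),
                     class = "coils_profile"))
  }
  # For window start i and frame f, residue j has phase (j - i + f) mod 7,
  # which equals (j + t) mod 7 with t = (f - i) mod 7; maximizing over the
  # 7 frames is maximizing over the 7 global phase shifts t.
  m <- coils_shift_matrices(chars, config)
  lp <- m$lp; wv <- m$wv
  per_window_scores <- list()
  probabilities <- rep(0, n)
  for (w in config$window_widths) {
    if (n < w) {
      per_window_scores[[as.character(w)]] <- rep(0, n)
      next
    }
    nstart <- n - w + 1L
    start_log <- window_start_log_scores(lp, wv, w, n)
    # per-residue best over covering windows [j-w+1, j] ∩ [1, nstart]
    res_log <- vapply(seq_len(n), function(j) {
      lo <- max(1L, j - w + 1L); hi <- min(j, nstart)
      if (lo > hi) -Inf else max(start_log[lo:hi])
    }, numeric(1))
    score <- exp(res_log)
    per_window_scores[[as.character(w)]] <- score
    g <- config$gauss[config$gauss$width == w, ]
    lcc <- stats::dnorm(score, g$cc_mean, g$cc_sd, log = TRUE)
    lgl <- stats::dnorm(score, g$glob_mean, g$glob_sd, log = TRUE)
    p <- 1 / (1 + exp(lgl - lcc))
    probabilities <- pmax(probabilities, p)
  }
  structure(list(probabilities = probabilities,
                 per_window_scores = per_window_scores,
                 too_short = FALSE),
            class = "coils_profile")
}

#' Aggregate a coiled-coil profile over the K span
#'
#' @param profile a [coils_profile()].
#' @param k_span 0-based half-open `c(start, end)` within the profile.
#' @return Numeric length 3: mean probability over the span, max
#'   probability, fraction of span positions with probability >= 0.5.
#' @export
encode_coils_block <- function(profile, k_span) {
  stopifnot(length(k_span) == 2L)
  start <- k_span[1]; end <- k_span[2]
  if (end <= start) stop("empty K span", call. = FALSE)
  if (start < 0 || end > length(profile$probabilities)) {
    stop("K span outside profile bounds", call. = FALSE)
  }
  p <- profile$probabilities[(start + 1L):end]
  c(mean(p), max(p), mean(p >= 0.5))
}
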