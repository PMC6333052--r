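# background amino-acid composition used by the generator (typical
# globular protein frequencies)
aa_background <- function() {
  bg <- c(A = .083, R = .055, N = .041, D = .055, C = .014, Q = .039,
          E = .067, G = .071, H = .022, I = .059, L = .096, K = .058,
          M = .024, F = .039, P = .047, S = .066, T = .053, W = .011,
          Y = .029, V = .069)
  bg / sum(bg)
}

# BLOSUM62-conditional replacement probabilities: P(b | a) proportional to
# exp(s_ab / 2) over b != a. Keeps simulated substitutions biochemically
# plausible so that alignment statistics (and the e-value gate) behave as
# they would on real families.
blosum_replacement_matrix <- function() {
  m <- get_blosum62()[AA20, AA20]
  p <- exp(m / 2)
  diag(p) <- 0
  sweep(p, 1, rowSums(p), "/")
}

# class-specific signature 8-mers planted in the C region: guaranteed,
# mutation-exempt class signal emulating the C domain's role as the most
# discriminative region
class_signatures <- function() {
  c(A    = "WCHFWMHY",
    B12  = "FWYCHMCW",
    B34  = "HMWYFCWH",
    BPI  = "CYHWMFYC",
    C    = "MHCWYWFH",
    D    = "YFMCHWHW",
    E    = "WHYMCFCY",
    AGL6 = "CWFHYHMW")
}

#' Specification of a synthetic eight-class MIKC family
#'
#' Defines the study conditions the generator emulates: fixed region
#' lengths (M=57, I=30, K=70, C=60), a within-class substitution rate of
#' 0.10 per site, and per-region between-class extra rates (M=0.05,
#' I=0.25, K=0.20, C=0.40) that reproduce the C > I > K > M diversity
#' ordering of real MIKC families. The M region always carries a match of
#' the configured PROSITE pattern and the K region is built from heptad
#' repeats with hydrophobic a/d positions.
#'
#' @param n_per_class members per class (>= 2; default 10).
#' @param region_lengths named integer vector over `M`, `I`, `K`, `C_TERM`.
#' @param within_class_sub_rate per-site substitution rate from the class
#'   ancestor to each member.
#' @param between_class_extra_rate named per-region rates from the root to
#'   each class ancestor.
#' @param heptad_in_k build the K region from heptad repeats.
#' @param m_pattern PROSITE pattern planted at the start of the M region.
#' @param seed mandatory integer seed.
#' @return A `family_spec`.
#' @export
family_spec <- function(n_per_class = 10L,
                        region_lengths = c(M = 57L, I = 30L, K = 70L,
                                           C_TERM = 60L),
                        within_class_sub_rate = 0.10,
                        between_class_extra_rate = c(M = 0.05, I = 0.25,
                                                     K = 0.20, C_TERM = 0.40),
                        heptad_in_k = TRUE,
                        m_pattern = default_m_pattern(),
                        seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.character(m_pattern)) m_pattern <- parse_prosite(m_pattern)
  tags <- region_tags(include_whole = FALSE)
  stopifnot(n_per_class >= 2, all(tags %in% names(region_lengths)),
            all(tags %in% names(between_class_extra_rate)),
            within_class_sub_rate >= 0, within_class_sub_rate < 1,
            all(between_class_extra_rate >= 0),
            all(between_class_extra_rate < 1))
  min_pat <- sum(vapply(m_pattern$elements, `[[`, integer(1), "min"))
  if (region_lengths[["M"]] < min_pat) {
    stop("M region shorter than the pattern minimum (", min_pat, ")",
         call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 region_lengths = vapply(region_lengths[tags], as.integer,
                                         integer(1)),
                 within_class_sub_rate = within_class_sub_rate,
                 between_class_extra_rate = between_class_extra_rate[tags],
                 heptad_in_k = isTRUE(heptad_in_k),
                 m_pattern = m_pattern,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# instantiate the pattern with min repeat counts (one residue per element
# occurrence, sampled uniformly from the allowed set)
instantiate_pattern <- function(pattern, bg) {
  unlist(lapply(pattern$elements, function(el) {
    n <- el$min
    if (n == 0L) return(character(0))
    if (el$kind == "any") {
      sample(names(bg), n, replace = TRUE, prob = bg)
    } else {
      sample(rep(el$set, 2L), n, replace = TRUE)
    }
  }))
}

# force the pattern to match at position 1 of chars: resample any
# violating residue from the element's allowed set
repair_pattern_site <- function(chars, pattern) {
  pos <- 1L
  for (el in pattern$elements) {
    for (r in seq_len(el$min)) {
      if (el$kind == "set" && !(chars[pos] %in% el$set)) {
        chars[pos] <- sample(rep(el$set, 2L), 1L)
      }
      pos <- pos + 1L
    }
  }
  chars
}

mutate_chars <- function(chars, rate, repl) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    if (chars[i] %in% AA20) {
      chars[i] <- sample(AA20, 1L, prob = repl[chars[i], ])
    }
  }
  chars
}

heptad_region <- function(len) {
  core <- c(L = 0.45, I = 0.2, V = 0.15, M = 0.1, A = 0.1)
  outer <- c(E = 0.22, K = 0.2, Q = 0.14, R = 0.1, A = 0.1, S = 0.08,
             N = 0.08, D = 0.08)
  vapply(seq_len(len) - 1L, function(j) {
    ph <- j %% 7L
    if (ph %in% c(0L, 3L)) sample(names(core), 1L, prob = core)
    else sample(names(outer), 1L, prob = outer)
  }, character(1))
}

#' Generate a synthetic eight-class MIKC family
#'
#' Eight class ancestors diverge from a common root by per-region extra
#' substitutions; members diverge from their ancestor at the within-class
#' rate. All substitutions are BLOSUM62-conditional. The M pattern site
#' and the class-signature 8-mer in the C region are repaired/re-planted
#' after mutation, so every sequence is pattern-positive and every class
#' keeps its C-region signal. Deterministic per seed.
#'
#' @param spec a [family_spec()].
#' @return A `labeled_dataset` with true [domain_annotation()]s.
#' @export
generate_families <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, {
    bg <- aa_background()
    repl <- blosum_replacement_matrix()
    rl <- spec$region_lengths
    tags <- region_tags(include_whole = FALSE)
    offsets <- c(0L, cumsum(rl))[1:4]
    names(offsets) <- tags
    total <- sum(rl)
    spans <- lapply(tags, function(tg) {
      c(offsets[[tg]], offsets[[tg]] + rl[[tg]])
    })
    names(spans) <- tags

    pat_chars <- instantiate_pattern(spec$m_pattern, bg)
    root <- character(total)
    root[spans$M[1] + seq_along(pat_chars)] <- pat_chars
    rest_m <- (spans$M[1] + length(pat_chars) + 1L):spans$M[2]
    root[rest_m] <- sample(names(bg), length(rest_m), replace = TRUE, prob = bg)
    idx_i <- (spans$I[1] + 1L):spans$I[2]
    root[idx_i] <- sample(names(bg), length(idx_i), replace = TRUE, prob = bg)
    idx_k <- (spans$K[1] + 1L):spans$K[2]
    root[idx_k] <- if (spec$heptad_in_k) heptad_region(rl[["K"]]) else
      sample(names(bg), rl[["K"]], replace = TRUE, prob = bg)
    idx_c <- (spans$C_TERM[1] + 1L):spans$C_TERM[2]
    root[idx_c] <- sample(names(bg), rl[["C_TERM"]], replace = TRUE, prob = bg)

    sigs <- class_signatures()
    sig_at <- spans$C_TERM[1] + 10L  # 0-based offset of the signature

    ids <- character(0); residues <- character(0); labels <- character(0)
    for (cls in gene_classes()) {
      anc <- root
      for (tg in tags) {
        idx <- (spans[[tg]][1] + 1L):spans[[tg]][2]
        anc[idx] <- mutate_chars(anc[idx],
                                 spec$between_class_extra_rate[[tg]], repl)
      }
      anc <- repair_pattern_site(anc, spec$m_pattern)
      sig <- strsplit(sigs[[cls]], "")[[1]]
      anc[sig_at + seq_along(sig)] <- sig
      for (member in seq_len(spec$n_per_class)) {
        chars <- mutate_chars(anc, spec$within_class_sub_rate, repl)
        chars <- repair_pattern_site(chars, spec$m_pattern)
        chars[sig_at + seq_along(sig)] <- sig
        ids <- c(ids, sprintf("%s_%02d", cls, member))
        residues <- c(residues, paste(chars, collapse = ""))
        labels <- c(labels, cls)
      }
    }
    seqs <- protein_set(ids, residues,
                        description = paste("synthetic", labels, "member"),
                        normalize = FALSE)
    annotations <- stats::setNames(lapply(seq_along(ids), function(i) {
      domain_annotation(ids[i], spans, seq_length = total)
    }), ids)
    labeled_dataset(sprintf("synthetic-families-seed%d", spec$seed),
                    seqs, stats::setNames(labels, ids), annotations)
  })
}

#' Truncate a sequence to a contiguous set of domains
#'
#' @param residues residue string.
#' @param true_annotation the sequence's [domain_annotation()].
#' @param keep region tags to keep; must be present in the annotation and
#'   contiguous in M < I < K < C_TERM order.
#' @return List with `residues` (the fragment) and `annotation` (spans
#'   shifted to fragment coordinates).
#' @export
truncate_to_domains <- function(residues, true_annotation, keep) {
  tags <- region_tags(include_whole = FALSE)
  keep <- tags[tags %in% keep]
  if (!length(keep)) stop("keep must name at least one region", call. = FALSE)
  if (!all(keep %in% names(true_annotation$spans))) {
    stop("region(s) absent from annotation: ",
         paste(setdiff(keep, names(true_annotation$spans)), collapse = ", "),
         call. = FALSE)
  }
  pos <- match(keep, tags)
  if (!identical(pos, seq(min(pos), max(pos)))) {
    stop("keep must be contiguous in M<I<K<C_TERM order", call. = FALSE)
  }
  frag <- ""
  new_spans <- list()
  at <- 0L
  for (tg in keep) {
    sp <- true_annotation$spans[[tg]]
    len <- sp[2] - sp[1]
    frag <- paste0(frag, substr(residues, sp[1] + 1L, sp[2]))
    new_spans[[tg]] <- c(at, at + len)
    at <- at + len
  }
  list(residues = frag,
       annotation = domain_annotation(true_annotation$sequence_id, new_spans,
                                      seq_length = at))
}

fragment_keeps <- function() {
  list(M = "M", MI = c("M", "I"), MIK = c("M", "I", "K"),
       MIKC = c("M", "I", "K", "C_TERM"), KC = c("K", "C_TERM"),
       C = "C_TERM")
}

#' Synthetic train/test benchmark bundle
#'
#' Generates a family per `spec`, splits it stratified 80/20, and derives
#' per-domain-content fragment test sets (keys M, MI, MIK, MIKC, KC, C)
#' from the held-out 20%. Deterministic per seed.
#'
#' @param spec a [family_spec()].
#' @param test_fraction held-out fraction (default 0.2).
#' @return List with `full` (the complete dataset), `train`, `test_full`,
#'   `fragments` (named list of `labeled_dataset`s keyed by domain
#'   content), and `spec`.
#' @export
benchmark_bundle <- function(spec, test_fraction = 0.2) {
  ds <- generate_families(spec)
  withr::with_seed(spec$seed + 1L, {
    test_ids <- unlist(lapply(gene_classes(), function(cls) {
      ids <- ds$seqs$id[ds$labels[ds$seqs$id] == cls]
      n_test <- max(1L, round(length(ids) * test_fraction))
      sample(ids, n_test)
    }))
  })
  train_ids <- setdiff(ds$seqs$id, test_ids)
  train <- subset_dataset(ds, train_ids, name = paste0(ds$name, "-train"))
  test_full <- subset_dataset(ds, test_ids, name = paste0(ds$name, "-test"))
  fragments <- lapply(names(fragment_keeps()), function(key) {
    keep <- fragment_keeps()[[key]]
    frs <- lapply(test_ids, function(id) {
      i <- match(id, ds$seqs$id)
      truncate_to_domains(ds$seqs$residues[i], ds$annotations[[id]], keep)
    })
    seqs <- protein_set(test_ids,
                        vapply(frs, `[[`, character(1), "residues"),
                        description = paste("fragment", key),
                        normalize = FALSE)
    labeled_dataset(paste0(ds$name, "-frag-", key), seqs,
                    ds$labels[test_ids],
                    stats::setNames(lapply(frs, `[[`, "annotation"), test_ids),
                    require_all_classes = FALSE)
  })
  names(fragments) <- names(fragment_keeps())
  list(full = ds, train = train, test_full = test_full,
       fragments = fragments, spec = spec)
}
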