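#' Position weight matrix (PWM) objects
#'
#' Builds a `pwm` object from a 4 x L matrix of per-position base
#' frequencies (rows A, C, G, T). A small pseudocount is added to every
#' cell and columns are renormalised so that logarithmic terms in the
#' information vector stay finite; `pseudocount = 0` is allowed and keeps
#' the frequencies untouched.
#'
#' @param freqs numeric 4 x L matrix (or L x 4, auto-transposed) of base
#'   frequencies; columns must each sum to a positive value.
#' @param id motif identifier.
#' @param tf_name transcription factor name (defaults to `id`).
#' @param kind `"monomer"` or `"dimer"`; dimer motifs are ordinary
#'   concatenated PWMs and are scored identically.
#' @param pseudocount probability mass added to each cell before
#'   renormalisation (default `1e-3`).
#' @return an object of class `pwm`: a list with elements `id`, `tf_name`,
#'   `kind`, `freqs` (4 x L, rows named A,C,G,T, columns summing to 1) and
#'   `pseudocount`.
#' @examples
#' p <- pwm(matrix(c(.7, .1, .1, .1, .25, .25, .25, .25), nrow = 4), "m1")
#' match_score(p, "AA")
#' @export
pwm <- function(freqs, id, tf_name = id, kind = c("monomer", "dimer"),
                pseudocount = 1e-3) {
  kind <- match.arg(kind)
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4 && ncol(freqs) == 4) freqs <- t(freqs)
  if (nrow(freqs) != 4) stop("'freqs' must have 4 rows (A, C, G, T)")
  if (ncol(freqs) < 1) stop("PWM must have at least one position")
  if (any(freqs < 0) || any(!is.finite(freqs))) {
    stop("PWM frequencies must be finite and non-negative")
  }
  if (any(colSums(freqs) <= 0)) stop("each PWM column must have positive mass")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  freqs <- freqs + pseudocount
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  dimnames(freqs) <- list(c("A", "C", "G", "T"), NULL)
  structure(
    list(id = as.character(id), tf_name = as.character(tf_name),
         kind = kind, freqs = freqs, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s, %s), %d positions, consensus %s\n",
              x$id, x$tf_name, x$kind, pwm_length(x), consensus(x)))
  print(round(x$freqs, 3))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm` object.
#' @export
pwm_length <- function(x) ncol(x$freqs)

#' Consensus and anti-consensus sequences of a PWM
#'
#' The consensus takes the most frequent base at every position (ties go to
#' the alphabetically first base) and by construction attains MATCH score 1;
#' the anti-consensus takes the least frequent base and attains score 0.
#'
#' @param x a `pwm` object.
#' @return a character scalar.
#' @export
consensus <- function(x) {
  paste(rownames(x$freqs)[apply(x$freqs, 2, which.max)], collapse = "")
}

#' @rdname consensus
#' @export
anti_consensus <- function(x) {
  paste(rownames(x$freqs)[apply(x$freqs, 2, which.min)], collapse = "")
}

#' Per-position information vector of a PWM
#'
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))`, with zero-frequency terms
#' contributing 0. A uniform column carries no information (0); a
#' deterministic column carries the maximum, ln 4.
#'
#' @param pwm a `pwm` object.
#' @return numeric vector of length `pwm_length(pwm)`, entries in
#'   `[0, ln 4]`.
#' @export
information_vector <- function(pwm) {
  f <- pwm$freqs
  term <- ifelse(f > 0, f * log(4 * f), 0)
  colSums(term)
}

# Information-weighted per-base score matrix W[b, i] = I(i) * f(i, b),
# plus the per-window min and max attainable raw scores.
pwm_weights <- function(pwm) {
  iv <- information_vector(pwm)
  w <- sweep(pwm$freqs, 2, iv, "*")
  list(w = w, min = sum(apply(w, 2, min)), max = sum(apply(w, 2, max)))
}

#' MATCH similarity score of a DNA window against a PWM
#'
#' The raw score of window `b_1..b_L` is `sum_i I(i) * f(i, b_i)`; it is
#' min-max normalised by the least and greatest raw scores attainable over
#' all windows, giving a similarity in `[0, 1]`. The consensus scores
#' exactly 1 and the per-position-minimal window exactly 0. A PWM whose
#' columns are all uniform carries no information; every window is then
#' both consensus and anti-consensus and is scored 1.
#'
#' @param pwm a `pwm` object.
#' @param window DNA string of length `pwm_length(pwm)`; bases must be
#'   A/C/G/T (ambiguity codes are rejected).
#' @return numeric score in `[0, 1]`.
#' @export
match_score <- function(pwm, window) {
  codes <- encode_dna(window)
  if (length(codes) != pwm_length(pwm)) {
    stop(sprintf("window length %d does not match PWM length %d",
                 length(codes), pwm_length(pwm)))
  }
  if (anyNA(codes)) stop("window contains a non-A/C/G/T base")
  wt <- pwm_weights(pwm)
  raw <- sum(wt$w[cbind(codes, seq_along(codes))])
  if (wt$max - wt$min < 1e-12) return(1)
  (raw - wt$min) / (wt$max - wt$min)
}

# Score every length-L window of an encoded sequence in one vectorised
# pass; windows containing non-ACGT bases come back NA.
score_windows <- function(pwm, codes) {
  L <- pwm_length(pwm)
  m <- length(codes)
  if (m < L) return(numeric(0))
  wt <- pwm_weights(pwm)
  n_win <- m - L + 1L
  raw <- numeric(n_win)
  for (i in seq_len(L)) {
    raw <- raw + wt$w[cbind(codes[i:(n_win + i - 1L)], i)]
  }
  if (wt$max - wt$min < 1e-12) return(ifelse(is.na(raw), NA_real_, 1))
  (raw - wt$min) / (wt$max - wt$min)
}

#' Relative affinity drop between reference and alternate windows
#'
#' Computes the fractional loss of MATCH score when the reference window is
#' replaced by the variant window:
#' `(score_ref - score_alt) / score_ref` (the default, relative mode), or
#' the plain difference `score_ref - score_alt` in absolute mode. Negative
#' values are affinity gains. A site whose reference score is 0 cannot be
#' polarised and returns `NA` (unscoreable).
#'
#' @param pwm a `pwm` object.
#' @param ref_window,alt_window DNA strings of the motif's length.
#' @param relative if `TRUE` (default) report the drop as a fraction of the
#'   reference score.
#' @return numeric drop (fraction or absolute difference), `NA` if the
#'   reference window scores 0 in relative mode.
#' @export
affinity_drop <- function(pwm, ref_window, alt_window, relative = TRUE) {
  s_ref <- match_score(pwm, ref_window)
  s_alt <- match_score(pwm, alt_window)
  if (!relative) return(s_ref - s_alt)
  if (s_ref <= 0) return(NA_real_)
  (s_ref - s_alt) / s_ref
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and complements the base frequencies
#' (A with T, C with G). Applying it twice restores the input; scanning the
#' reverse strand of a sequence with a PWM is equivalent to scanning the
#' forward strand with its reverse complement.
#'
#' @param pwm a `pwm` object.
#' @return a `pwm` object.
#' @export
reverse_complement_pwm <- function(pwm) {
  f <- pwm$freqs[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$freqs))), drop = FALSE]
  rownames(f) <- c("A", "C", "G", "T")
  out <- pwm
  out$freqs <- f
  out
}

#' CpG-preserving column shuffle of a PWM
#'
#' Permutes the PWM's columns while keeping every CpG consensus
#' dinucleotide intact: any adjacent column pair whose consensus bases are
#' C then G is glued together and moved as a unit, in order. The multiset
#' of columns (and hence the attainable score range and information
#' content) is unchanged. Deterministic given `seed`.
#'
#' @param pwm a `pwm` object with at least 1 position (length-1 PWMs are
#'   returned unchanged).
#' @param seed integer seed.
#' @return a `pwm` object with id suffixed `_shuf`.
#' @export
shuffle_pwm_preserve_cpg <- function(pwm, seed) {
  L <- pwm_length(pwm)
  if (L < 2) return(pwm)
  cons <- strsplit(consensus(pwm), "", fixed = TRUE)[[1]]
  # glue i to i+1 when consensus is C,G; pairs cannot chain (a column
  # cannot be both the G of one pair and the C of the next)
  glue <- cons[-L] == "C" & cons[-1] == "G"
  units <- list()
  i <- 1L
  while (i <= L) {
    if (i < L && glue[i]) {
      units[[length(units) + 1L]] <- c(i, i + 1L)
      i <- i + 2L
    } else {
      units[[length(units) + 1L]] <- i
      i <- i + 1L
    }
  }
  perm <- with_seed(seed, sample(length(units)))
  cols <- unlist(units[perm])
  out <- pwm
  out$freqs <- pwm$freqs[, cols, drop = FALSE]
  out$id <- paste0(pwm$id, "_shuf")
  out
}
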