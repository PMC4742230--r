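#' Medical history sets and association matrices
#'
#' A history set maps each person to their list of medical-history
#' entries (free-text labels, duplicates across persons allowed). The
#' association matrix links history entries (rows) to top enriched terms
#' (columns) with 0/1 cells; it is the "gold" standard against which
#' shuffled histories are scored.
#'
#' @param path 2-column TSV with header `person`, `entry`.
#' @return named list person -> character vector of entries.
#' @export
read_histories <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("person", "entry") %in% names(df)))
  if (any(!nzchar(df$entry))) stop("empty history entry")
  split(df$entry, df$person)
}

#' @rdname read_histories
#' @param histories named list person -> entries.
#' @export
write_histories <- function(histories, path) {
  df <- data.frame(person = rep(names(histories), lengths(histories)),
                   entry = unlist(histories, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an association matrix
#'
#' TSV grid: header row of term ids, first column of history entries,
#' cells 0/1.
#'
#' @param path TSV file.
#' @return logical matrix, rownames = entries, colnames = terms.
#' @export
read_association_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df) != 0
  storage.mode(m) <- "logical"
  m
}

#' @rdname read_association_matrix
#' @param matrix logical matrix (entries x terms).
#' @export
write_association_matrix <- function(matrix, path) {
  df <- data.frame(entry = rownames(matrix),
                   matrix * 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# all (person, entry) pairs of a history set as "person\036entry" strings
history_pairs <- function(histories) {
  unlist(lapply(names(histories), function(p)
    paste(p, histories[[p]], sep = "\036")), use.names = FALSE)
}

#' Constrained shuffle of medical histories
#'
#' Permutes the pooled history entries across persons while (i) keeping
#' every person's entry count exactly as observed, (ii) keeping the
#' global multiset of entries (each entry label's frequency) unchanged,
#' and (iii) requiring at least `min_diff_frac` of the (person, entry)
#' pairings to differ from the original. Entries are redrawn (bounded
#' attempts) until the difference constraint holds. Deterministic given
#' `seed`.
#'
#' @param histories named list person -> entries (at least 2 persons).
#' @param seed integer seed.
#' @param min_diff_frac minimum fraction of changed pairings
#'   (default 0.8).
#' @param max_attempts resampling bound (default 1000).
#' @return a shuffled history set with the same names and entry counts.
#' @export
shuffle_histories <- function(histories, seed, min_diff_frac = 0.8,
                              max_attempts = 1000) {
  if (length(histories) < 2) stop("need at least 2 persons to shuffle")
  persons <- names(histories)
  counts <- lengths(histories)
  pool <- unlist(histories, use.names = FALSE)
  orig <- lapply(histories, function(e) table(e))
  n_pairs <- length(pool)
  result <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      perm <- sample(pool)
      out <- split(perm, rep(persons, counts))[persons]
      # pairs unchanged = per person, overlap between old and new multiset
      same <- sum(vapply(persons, function(p) {
        new_tab <- table(out[[p]])
        common <- intersect(names(new_tab), names(orig[[p]]))
        sum(pmin(new_tab[common], orig[[p]][common]))
      }, numeric(1)))
      if ((n_pairs - same) / n_pairs >= min_diff_frac) {
        found <- out
        break
      }
    }
    found
  })
  if (is.null(result)) {
    stop("could not satisfy the history-shuffle constraints after ",
         max_attempts, " attempts")
  }
  result
}

#' Does a person-to-term assignment agree with the association matrix?
#'
#' By default every person's top term must be linked (a `TRUE` cell) to
#' at least one of that person's history entries; `min_matches` relaxes
#' the requirement to at least k persons.
#'
#' @param tops named character vector person -> top term.
#' @param histories named list person -> entries.
#' @param matrix logical association matrix (entries x terms).
#' @param min_matches number of persons that must match (default: all).
#' @return logical scalar.
#' @export
set_is_associated <- function(tops, histories, matrix,
                              min_matches = length(tops)) {
  persons <- names(tops)
  ok <- vapply(persons, function(p) {
    entries <- histories[[p]]
    term <- tops[[p]]
    if (!term %in% colnames(matrix)) stop("term missing from matrix: ", term)
    missing <- setdiff(entries, rownames(matrix))
    if (length(missing)) {
      stop("history entries missing from matrix: ",
           paste(missing, collapse = ", "))
    }
    any(matrix[entries, term])
  }, logical(1))
  sum(ok) >= min_matches
}

#' Empirical p-value for the enrichment-medical history association
#'
#' Shuffles the histories `n_shuffles` times under the constraints of
#' [shuffle_histories()] and counts how often the shuffled person-history
#' sets are still associated with the observed top terms under the gold
#' association matrix; `p = n_hits / n_shuffles`.
#'
#' @inheritParams set_is_associated
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed master seed; shuffle `k` uses seed `seed + k`.
#' @param min_diff_frac passed to [shuffle_histories()].
#' @param min_matches passed to [set_is_associated()].
#' @return an `empirical_result` (see [empirical_top_term_p()]).
#' @export
association_empirical_p <- function(histories, tops, matrix,
                                    n_shuffles = 1000, seed = 1,
                                    min_diff_frac = 0.8,
                                    min_matches = length(tops)) {
  if (!set_is_associated(tops, histories, matrix, min_matches)) {
    warning("the observed set is not associated under the matrix; ",
            "the empirical test is moot")
  }
  hits <- 0L
  for (k in seq_len(n_shuffles)) {
    shuf <- shuffle_histories(histories, derive_seed(seed, k),
                              min_diff_frac = min_diff_frac)
    if (set_is_associated(tops, shuf, matrix, min_matches)) hits <- hits + 1L
  }
  structure(list(n_shuffles = n_shuffles, n_hits = hits,
                 p = hits / n_shuffles),
            class = "empirical_result")
}
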