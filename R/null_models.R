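#' Matched-control pool of conserved binding sites
#'
#' Indexes the conserved-site universe by
#' `(motif id, MATCH score rounded to 2 decimals, floor(log10 conservation p))`
#' so that for any eroded site a control with the same motif, identical
#' binding affinity and a conservation p-value of the same order of
#' magnitude can be drawn. Every site falls in exactly one bucket.
#'
#' @param sites conserved-site data.frame (the full universe, see
#'   [filter_conserved()]).
#' @return object of class `control_pool`: list with the `sites` table
#'   and a bucket index.
#' @export
build_control_pool <- function(sites) {
  key <- control_key(sites$motif_id, sites$score, sites$conservation_p)
  structure(list(sites = sites, key = key,
                 index = split(seq_len(nrow(sites)), key)),
            class = "control_pool")
}

control_key <- function(motif_id, score, conservation_p) {
  sprintf("%s|%.2f|%d", motif_id, round(score, 2),
          floor(log10(conservation_p)))
}

#' @export
print.control_pool <- function(x, ...) {
  cat(sprintf("Control pool: %d sites in %d buckets\n",
              nrow(x$sites), length(x$index)))
  invisible(x)
}

#' Sample one size-matched control set for a CoBEL set
#'
#' Draws, for each eroded locus, one conserved site uniformly from the
#' bucket matching that locus's representative site (same motif, same
#' affinity to 2 decimals, same conservation-p order of magnitude). The
#' locus's own site is excluded when the bucket offers alternatives; an
#' empty bucket falls back to the same-motif site with the nearest score
#' (logged). Deterministic given `seed`.
#'
#' @param cobels a `cobel_set` (see [call_cobels()]); needs
#'   `site_start`/`site_end` or `start`/`end`, `motif_id`,
#'   `ancestral_score` and `conservation_p` per locus — loci carry their
#'   representative site's score and conservation p (see
#'   [attach_site_conservation()]).
#' @param pool a `control_pool` built from the full site universe.
#' @param seed integer seed.
#' @return data.frame of sampled control sites, one row per CoBEL.
#' @export
sample_matched_control_set <- function(cobels, pool, seed) {
  n <- nrow(cobels)
  sites <- pool$sites
  idx_out <- integer(n)
  keys <- control_key(cobels$motif_id, cobels$ancestral_score,
                      cobels$conservation_p)
  site_start <- cobels$site_start %||% cobels$start
  with_seed(seed, {
    for (i in seq_len(n)) {
      bucket <- pool$index[[keys[i]]]
      self <- which(sites$motif_id[bucket] == cobels$motif_id[i] &
                      sites$chrom[bucket] == cobels$chrom[i] &
                      sites$start[bucket] == site_start[i])
      choices <- if (length(self) && length(bucket) > length(self)) {
        bucket[-self]
      } else {
        bucket
      }
      if (!length(choices)) {
        same_motif <- which(sites$motif_id == cobels$motif_id[i])
        if (!length(same_motif)) {
          stop("no conserved site shares motif ", cobels$motif_id[i])
        }
        cobel_log(sprintf(
          "sample_matched_control_set: empty bucket for %s, falling back to nearest-score site",
          keys[i]))
        d <- abs(sites$score[same_motif] - cobels$ancestral_score[i])
        choices <- same_motif[d == min(d)]
      }
      idx_out[i] <- if (length(choices) == 1) choices
                    else choices[sample.int(length(choices), 1)]
    }
  })
  out <- sites[idx_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach conservation metadata of representative sites to CoBELs
#'
#' Looks each locus's representative site up in the conserved-site table
#' and copies its conservation p-value (needed for matched-control
#' sampling).
#'
#' @param cobels a `cobel_set`.
#' @param sites the conserved-site table the loci were called from.
#' @return `cobels` with a `conservation_p` column.
#' @export
attach_site_conservation <- function(cobels, sites) {
  key_c <- paste(cobels$chrom, cobels$site_start, cobels$site_end,
                 cobels$strand, cobels$motif_id)
  key_s <- paste(sites$chrom, sites$start, sites$end, sites$strand,
                 sites$motif_id)
  m <- match(key_c, key_s)
  if (anyNA(m)) stop("representative site missing from conserved-site table")
  cobels$conservation_p <- sites$conservation_p[m]
  cobels
}

#' Empirical p-value of recovering the observed top term under shuffles
#'
#' Counts how many shuffled (matched-control) screens produced a top
#' enrichment inside the target term set; shuffles with no passing term
#' are counted in the denominator but never as hits. The p-value is the
#' plain hit fraction `n_hits / n_shuffles`.
#'
#' @param observed_top the observed top term id.
#' @param shuffle_tops character vector of top terms from the shuffled
#'   screens (`NA` for shuffles with no passing term).
#' @param target_set character vector of term ids counted as a hit
#'   (the observed term itself, or its related-term group).
#' @return list of class `empirical_result`: `n_shuffles`, `n_hits`, `p`.
#' @export
empirical_top_term_p <- function(observed_top, shuffle_tops, target_set) {
  if (!observed_top %in% target_set) {
    warning("observed top term is not in the target set")
  }
  n_hits <- sum(!is.na(shuffle_tops) & shuffle_tops %in% target_set)
  structure(list(n_shuffles = length(shuffle_tops), n_hits = n_hits,
                 p = n_hits / length(shuffle_tops)),
            class = "empirical_result")
}

#' @export
print.empirical_result <- function(x, ...) {
  cat(sprintf("Empirical p = %.4g (%d/%d shuffles)\n",
              x$p, x$n_hits, x$n_shuffles))
  invisible(x)
}

#' Run the matched-control null for one screen
#'
#' Draws `n_shuffles` size-matched control sets, submits each to the
#' enrichment engine, records the top term of each, and returns the
#' empirical p-value for recovering `target_set`.
#'
#' @param cobels a `cobel_set` with `conservation_p` attached.
#' @param pool a `control_pool` over the conserved-site universe.
#' @param genes,chrom_sizes,ont,config enrichment inputs (see
#'   [great_enrichment()]).
#' @param target_set term ids counted as a hit.
#' @param n_shuffles number of control sets (the full-scale screen uses
#'   10,000; toy screens use a few hundred).
#' @param seed master seed; shuffle `k` uses seed `seed + k`.
#' @return list with the `empirical_result` (`$result`) and the vector of
#'   shuffle top terms (`$tops`).
#' @export
matched_control_null <- function(cobels, pool, genes, chrom_sizes, ont,
                                 config = great_config(), target_set,
                                 n_shuffles = 10000, seed = 1) {
  tops <- rep(NA_character_, n_shuffles)
  for (k in seq_len(n_shuffles)) {
    ctl <- sample_matched_control_set(cobels, pool, derive_seed(seed, k))
    res <- great_enrichment(ctl, genes, chrom_sizes, ont, config)
    top <- rank_and_select_top(res, config)
    if (!is.null(top)) tops[k] <- top$term
  }
  observed <- if (length(target_set)) target_set[1] else NA_character_
  list(result = empirical_top_term_p(observed, tops, target_set),
       tops = tops)
}

#' Product combination of independent empirical p-values
#'
#' @param ps numeric vector of p-values in `(0, 1]`.
#' @return their product.
#' @export
combine_pvalues_product <- function(ps) {
  if (!length(ps)) stop("no p-values to combine")
  stopifnot(all(ps > 0), all(ps <= 1))
  prod(ps)
}

#' Occurrence rate of a term set among cohort top enrichments
#'
#' @param target_set character vector of term ids.
#' @param cohort_tops per-genome top terms (`NA` = no passing term).
#' @return fraction of cohort genomes whose top term is in the set.
#' @export
occurrence_rate <- function(target_set, cohort_tops) {
  if (!length(cohort_tops)) stop("cohort is empty")
  sum(!is.na(cohort_tops) & cohort_tops %in% target_set) / length(cohort_tops)
}

#' Cohort allele frequency of CoBEL variants
#'
#' For each locus, the fraction of cohort genomes carrying the same
#' derived allele at the representative variant's position (any matching
#' `chrom:pos:alt` among the locus's contributing variants counts).
#'
#' @param cobels a `cobel_set`.
#' @param cohort_variant_sets list of variant data.frames (one per cohort
#'   genome, as from [load_variants()]).
#' @return numeric vector of frequencies in `[0, 1]`, one per locus.
#' @export
cohort_allele_frequency <- function(cobels, cohort_variant_sets) {
  n_genomes <- length(cohort_variant_sets)
  if (!n_genomes) stop("cohort is empty")
  cohort_keys <- lapply(cohort_variant_sets, function(v)
    unique(paste(v$chrom, v$pos, v$alt)))
  vapply(seq_len(nrow(cobels)), function(i) {
    ids <- strsplit(cobels$variant_ids[i], ",", fixed = TRUE)[[1]]
    # variant ids encode chrom:pos:REF>ALT
    parts <- strsplit(ids, "[:>]")
    keys <- vapply(parts, function(p) paste(p[1], p[2], p[4]), character(1))
    sum(vapply(cohort_keys, function(ck) any(keys %in% ck), logical(1))) /
      n_genomes
  }, numeric(1))
}

#' Filter CoBELs by cohort allele frequency
#'
#' @param cobels a `cobel_set`.
#' @param freqs frequencies from [cohort_allele_frequency()].
#' @param max_freq maximum cohort frequency to keep (e.g. 0.01 for rare
#'   loci).
#' @return the filtered `cobel_set`.
#' @export
filter_by_frequency <- function(cobels, freqs, max_freq) {
  stopifnot(length(freqs) == nrow(cobels))
  out <- cobels[freqs <= max_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}
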