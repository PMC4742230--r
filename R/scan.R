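#' Scan configuration for conserved binding site prediction
#'
#' Bundles the conservation-filter thresholds. Defaults follow the
#' screen's standard settings: at least five preserving species, total
#' preserving neutral branch length of at least two substitutions per
#' site, conservation p-value at most 0.05, and at most the top 5,000
#' sites per motif.
#'
#' @param min_species minimum number of non-reference species preserving
#'   a site (default 5).
#' @param min_branch_length minimum total preserving branch length,
#'   substitutions/site (default 2).
#' @param max_sites_per_motif per-motif cap on retained sites
#'   (default 5000).
#' @param max_conservation_p maximum shuffled-motif conservation p-value
#'   (default 0.05).
#' @param score_cutoff MATCH score threshold for calling a hit, in
#'   `[0, 1]` (default 0.9).
#' @param n_shuffles_for_p motif shuffles per site for the conservation
#'   p-value (default 19: the smallest count whose `(c+1)/(N+1)` p-value
#'   can reach the 0.05 filter).
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(min_species = 5, min_branch_length = 2.0,
                        max_sites_per_motif = 5000,
                        max_conservation_p = 0.05,
                        score_cutoff = 0.9, n_shuffles_for_p = 19) {
  stopifnot(min_species >= 0, min_branch_length >= 0,
            max_sites_per_motif >= 0, max_conservation_p >= 0,
            score_cutoff >= 0, score_cutoff <= 1, n_shuffles_for_p >= 1)
  structure(list(min_species = min_species,
                 min_branch_length = min_branch_length,
                 max_sites_per_motif = max_sites_per_motif,
                 max_conservation_p = max_conservation_p,
                 score_cutoff = score_cutoff,
                 n_shuffles_for_p = n_shuffles_for_p),
            class = "scan_config")
}

#' Read / write a genome as FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Scan a genome with a PWM on both strands
#'
#' Scores every window of every chromosome with the MATCH scheme, on the
#' forward strand with the PWM itself and on the reverse strand with its
#' reverse complement, and reports windows at or above `score_cutoff`.
#' Windows containing non-A/C/G/T bases are skipped. Coordinates are
#' 0-based half-open on the reference.
#'
#' @param pwm a [pwm] object.
#' @param genome named character vector of chromosome sequences (or a
#'   FASTA path).
#' @param score_cutoff minimum MATCH score for a reported hit.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `motif_id`, `tf`, `score`, sorted by coordinate.
#' @export
scan_reference <- function(pwm, genome, score_cutoff) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  L <- pwm_length(pwm)
  rc <- reverse_complement_pwm(pwm)
  out <- list()
  for (chrom in names(genome)) {
    codes <- encode_dna(genome[[chrom]])
    if (length(codes) < L) next
    for (strand in c("+", "-")) {
      sc <- score_windows(if (strand == "+") pwm else rc, codes)
      keep <- which(!is.na(sc) & sc >= score_cutoff)
      if (length(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = keep - 1L, end = keep - 1L + L,
          strand = strand, motif_id = pwm$id, tf = pwm$tf_name,
          score = sc[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      motif_id = character(), tf = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a genome with a whole motif library
#'
#' @param pwms list of [pwm] objects.
#' @inheritParams scan_reference
#' @return row-bound [scan_reference()] results.
#' @export
scan_genome <- function(pwms, genome, score_cutoff) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  res <- do.call(rbind, lapply(pwms, scan_reference, genome = genome,
                               score_cutoff = score_cutoff))
  rownames(res) <- NULL
  res
}

#' Species preserving a binding site in an alignment block
#'
#' A non-reference species preserves a site when its orthologous aligned
#' window is gap-free, contains only A/C/G/T, and attains MATCH score at
#' least `score_cutoff` on the site's strand.
#'
#' @param site a list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @param block one alignment block from [read_maf()] covering the site.
#' @param pwm the site's [pwm].
#' @param score_cutoff MATCH score threshold (the same cutoff as the
#'   reference scan).
#' @return character vector of preserving species (reference excluded).
#' @export
species_preserving_site <- function(site, block, pwm, score_cutoff) {
  if (site$start < block$start || site$end > block$end) {
    stop("site lies outside the alignment block")
  }
  cols <- ref_columns(block, site$start, site$end)
  scorer <- if (site$strand == "-") reverse_complement_pwm(pwm) else pwm
  wt <- pwm_weights(scorer)
  denom <- wt$max - wt$min
  kept <- character(0)
  for (i in seq_along(block$species)[-1]) {
    chars <- strsplit(block$seqs[i], "", fixed = TRUE)[[1]][cols]
    codes <- match(chars, DNA_BASES)
    if (anyNA(codes)) next  # gap or ambiguity in the window
    raw <- sum(wt$w[cbind(codes, seq_along(codes))])
    score <- if (denom < 1e-12) 1 else (raw - wt$min) / denom
    if (score >= score_cutoff) kept <- c(kept, block$species[i])
  }
  kept
}

# Best preserving branch length over all qualifying windows of `pwm`
# within one block (both strands). Stops early once `stop_at` is reached.
best_branch_length_in_block <- function(pwm, block, tree, score_cutoff,
                                        stop_at = Inf) {
  ref_seq <- gsub("-", "", block$seqs[1], fixed = TRUE)
  codes <- encode_dna(ref_seq)
  L <- pwm_length(pwm)
  if (length(codes) < L) return(0)
  hits <- list()
  for (strand in c("+", "-")) {
    scorer <- if (strand == "+") pwm else reverse_complement_pwm(pwm)
    sc <- score_windows(scorer, codes)
    keep <- which(!is.na(sc) & sc >= score_cutoff)
    if (length(keep)) {
      hits[[strand]] <- data.frame(start = block$start + keep - 1L,
                                   strand = strand, score = sc[keep])
    }
  }
  if (!length(hits)) return(0)
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$score), , drop = FALSE]
  best <- 0
  for (r in seq_len(nrow(hits))) {
    site <- list(chrom = block$chrom, start = hits$start[r],
                 end = hits$start[r] + L, strand = hits$strand[r])
    sp <- species_preserving_site(site, block, pwm, score_cutoff)
    bl <- preserved_branch_length(sp, tree)
    if (bl > best) best <- bl
    if (best >= stop_at) break
  }
  best
}

#' Shuffled-motif conservation p-value of a site
#'
#' Compares the site's preserving branch length against the best
#' preserving branch length attained by CpG-preserving shuffles of its
#' motif within the same alignment block (a locality-matched null for
#' regional conservation). The empirical p-value uses the `(c+1)/(N+1)`
#' estimator, so it is never 0 and is 1 when every shuffle ties or beats
#' the real site (e.g. a site preserved in no species).
#'
#' @param site list/one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` and optionally `branch_length` (recomputed when absent).
#' @param pwm the site's [pwm].
#' @param block the alignment block containing the site.
#' @param tree neutral phylogeny (see [read_phylo()]).
#' @param config a [scan_config()].
#' @param seed integer seed; shuffle `k` uses seed `seed + k`.
#' @return p-value in `(0, 1]`.
#' @export
conservation_pvalue <- function(site, pwm, block, tree, config, seed) {
  real_bl <- site$branch_length
  if (is.null(real_bl) || is.na(real_bl)) {
    sp <- species_preserving_site(site, block, pwm, config$score_cutoff)
    real_bl <- preserved_branch_length(sp, tree)
  }
  n <- config$n_shuffles_for_p
  c_ge <- 0L
  for (k in seq_len(n)) {
    shuf <- shuffle_pwm_preserve_cpg(pwm, derive_seed(seed, k))
    best <- best_branch_length_in_block(shuf, block, tree,
                                        config$score_cutoff,
                                        stop_at = real_bl)
    if (best >= real_bl) c_ge <- c_ge + 1L
  }
  (c_ge + 1) / (n + 1)
}

#' Annotate scan hits with conservation evidence
#'
#' For every hit, finds the alignment block fully containing it (hits
#' spanning block boundaries are dropped), counts preserving species,
#' sums their induced branch length, and — for hits already meeting the
#' species and branch-length thresholds — computes the shuffled-motif
#' conservation p-value. Hits failing the earlier thresholds get `NA`
#' p-values (they cannot survive [filter_conserved()] regardless).
#'
#' @param hits data.frame from [scan_genome()].
#' @param blocks a `maf_alignment` from [read_maf()].
#' @param pwms named list of [pwm] objects covering `hits$motif_id`.
#' @param tree neutral phylogeny.
#' @param config a [scan_config()].
#' @param seed integer seed for the conservation-p shuffles.
#' @return `hits` with added columns `n_species`, `branch_length`,
#'   `conservation_p`.
#' @export
annotate_conservation <- function(hits, blocks, pwms, tree, config, seed) {
  n <- nrow(hits)
  n_species <- integer(n)
  branch_length <- numeric(n)
  conservation_p <- rep(NA_real_, n)
  in_block <- logical(n)
  for (i in seq_len(n)) {
    bi <- find_block(blocks, hits$chrom[i], hits$start[i], hits$end[i])
    if (is.na(bi)) next
    in_block[i] <- TRUE
    block <- blocks[[bi]]
    pwm <- pwms[[hits$motif_id[i]]]
    site <- hits[i, ]
    sp <- species_preserving_site(site, block, pwm, config$score_cutoff)
    n_species[i] <- length(sp)
    branch_length[i] <- preserved_branch_length(sp, tree)
    if (n_species[i] >= config$min_species &&
        branch_length[i] >= config$min_branch_length) {
      site$branch_length <- branch_length[i]
      conservation_p[i] <- conservation_pvalue(
        site, pwm, block, tree, config,
        derive_seed(seed, i * (config$n_shuffles_for_p + 1L)))
    }
  }
  out <- hits[in_block, , drop = FALSE]
  out$n_species <- n_species[in_block]
  out$branch_length <- branch_length[in_block]
  out$conservation_p <- conservation_p[in_block]
  rownames(out) <- NULL
  out
}

#' Apply the conservation filters and per-motif cap
#'
#' Keeps hits with at least `min_species` preserving species, preserving
#' branch length at least `min_branch_length`, and conservation p-value
#' at most `max_conservation_p`; then, per motif, retains at most
#' `max_sites_per_motif` hits ranked by conservation p (ascending), MATCH
#' score (descending) and coordinate (ascending). Idempotent.
#'
#' @param hits data.frame from [annotate_conservation()].
#' @param config a [scan_config()].
#' @return filtered, ranked data.frame of conserved sites.
#' @export
filter_conserved <- function(hits, config) {
  keep <- !is.na(hits$n_species) & hits$n_species >= config$min_species &
    !is.na(hits$branch_length) &
    hits$branch_length >= config$min_branch_length &
    !is.na(hits$conservation_p) &
    hits$conservation_p <= config$max_conservation_p
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    rownames(out) <- NULL
    return(out)
  }
  parts <- split(out, out$motif_id)
  parts <- lapply(parts, function(d) {
    d <- d[order(d$conservation_p, -d$score, d$chrom, d$start), , drop = FALSE]
    head(d, config$max_sites_per_motif)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start, out$strand, out$motif_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read conserved sites as BED6+
#'
#' BED columns: chrom, start, end, name (motif id), score
#' (`round(1000 * match score)`), strand; extra columns: tf, match_score,
#' n_species, branch_length, conservation_p.
#'
#' @param sites conserved-site data.frame.
#' @param path output path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_conserved_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = sites$start,
                   end = sites$end, name = sites$motif_id,
                   score = round(1000 * sites$score), strand = sites$strand,
                   tf = sites$tf,
                   match_score = sprintf("%.6f", sites$score),
                   n_species = sites$n_species,
                   branch_length = sprintf("%.6f", sites$branch_length),
                   conservation_p = sprintf("%.6g", sites$conservation_p),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_conserved_bed
#' @export
read_conserved_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "bed_score",
                                 "strand", "tf", "match_score", "n_species",
                                 "branch_length", "conservation_p"))
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand, motif_id = df$name, tf = df$tf,
             score = as.numeric(df$match_score),
             n_species = df$n_species,
             branch_length = as.numeric(df$branch_length),
             conservation_p = as.numeric(df$conservation_p),
             stringsAsFactors = FALSE)
}
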