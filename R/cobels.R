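#' Calling configuration for conserved binding site eroding loci
#'
#' @param min_drop minimum relative MATCH-score drop for an erosion call
#'   (default 0.05, i.e. the derived allele loses at least 5\% of the
#'   ancestral binding affinity).
#' @param relative_drop if `TRUE` (default) the drop is relative to the
#'   ancestral score; if `FALSE` it is the absolute score difference.
#' @param outgroup_label free-text label of the ancestral proxy species,
#'   recorded in outputs.
#' @return a list of class `call_config`.
#' @export
call_config <- function(min_drop = 0.05, relative_drop = TRUE,
                        outgroup_label = "outgroup") {
  stopifnot(min_drop >= 0)
  structure(list(min_drop = min_drop, relative_drop = relative_drop,
                 outgroup_label = outgroup_label),
            class = "call_config")
}

empty_cobels <- function() {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       motif_id = character(), tf = character(),
                       site_start = integer(), site_end = integer(),
                       ancestral_score = numeric(), derived_score = numeric(),
                       drop = numeric(), zygosity = character(),
                       variant_ids = character(), n_sites = integer(),
                       stringsAsFactors = FALSE),
            class = c("cobel_set", "data.frame"))
}

#' Call conserved binding site eroding loci (CoBELs)
#'
#' Intersects conserved binding sites with an individual's (ancestrally
#' polarised) derived variants. For every site overlapped by at least one
#' variant, all of the individual's alternate alleles inside the window
#' are substituted jointly (a single derived haplotype) and the window is
#' rescored; sites losing at least `min_drop` of their ancestral MATCH
#' score become erosion candidates. Candidates overlapping in genomic
#' coordinates (either strand) are merged into one locus represented by
#' the site with the greatest drop (ties: higher ancestral score, then
#' leftmost). Sites whose stored reference window disagrees with a
#' variant's reference allele are logged and skipped.
#'
#' @param sites conserved-site data.frame (see [filter_conserved()]).
#' @param variants variant data.frame (see [ancestral_filter()]).
#' @param pwms named list of [pwm] objects covering `sites$motif_id`.
#' @param genome named character vector of reference sequences.
#' @param config a [call_config()].
#' @return a `cobel_set` data.frame, sorted by coordinate: one row per
#'   merged locus with the representative site's motif, scores, drop,
#'   worst-case zygosity and contributing variant ids.
#' @export
call_cobels <- function(sites, variants, pwms, genome, config = call_config()) {
  if (nrow(sites) == 0 || nrow(variants) == 0) return(empty_cobels())
  cand <- list()
  for (chrom in unique(sites$chrom)) {
    s_idx <- which(sites$chrom == chrom)
    v_idx <- which(variants$chrom == chrom)
    if (!length(v_idx)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$start[s_idx] + 1L, sites$end[s_idx]),
      IRanges::IRanges(variants$pos[v_idx] + 1L, variants$pos[v_idx] + 1L))
    if (!length(ov)) next
    by_site <- split(v_idx[S4Vectors::subjectHits(ov)],
                     s_idx[S4Vectors::queryHits(ov)])
    for (nm in names(by_site)) {
      i <- as.integer(nm)
      vs <- by_site[[nm]]
      site <- sites[i, ]
      pwm <- pwms[[site$motif_id]]
      ref_win <- toupper(substr(genome[[site$chrom]], site$start + 1L, site$end))
      offs <- variants$pos[vs] - site$start + 1L
      if (any(strsplit(ref_win, "", fixed = TRUE)[[1]][offs] != variants$ref[vs])) {
        cobel_log(sprintf(
          "call_cobels: variant/reference allele mismatch at %s:%d (site %s), site skipped",
          site$chrom, site$start, site$motif_id))
        next
      }
      alt_chars <- strsplit(ref_win, "", fixed = TRUE)[[1]]
      alt_chars[offs] <- variants$alt[vs]
      alt_win <- paste(alt_chars, collapse = "")
      scorer <- if (site$strand == "-") reverse_complement_pwm(pwm) else pwm
      drop <- affinity_drop(scorer, ref_win, alt_win,
                            relative = config$relative_drop)
      if (is.na(drop) || drop < config$min_drop) next
      s_ref <- match_score(scorer, ref_win)
      s_alt <- match_score(scorer, alt_win)
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = site$chrom, start = site$start, end = site$end,
        strand = site$strand, motif_id = site$motif_id, tf = site$tf,
        ancestral_score = s_ref, derived_score = s_alt, drop = drop,
        zygosity = if (any(variants$zygosity[vs] == "hom")) "hom" else "het",
        variant_ids = paste(variants$id[vs], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_cobels())
  cand <- do.call(rbind, cand)
  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1L, cand$end))
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  group <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  out <- lapply(split(seq_len(nrow(cand)), group), function(idx) {
    d <- cand[idx, , drop = FALSE]
    rep_i <- idx[order(-d$drop, -d$ancestral_score, d$start)][1]
    rep <- cand[rep_i, ]
    data.frame(
      chrom = rep$chrom, start = min(d$start), end = max(d$end),
      strand = rep$strand, motif_id = rep$motif_id, tf = rep$tf,
      site_start = rep$start, site_end = rep$end,
      ancestral_score = rep$ancestral_score,
      derived_score = rep$derived_score, drop = rep$drop,
      zygosity = if (any(d$zygosity == "hom")) "hom" else "het",
      variant_ids = paste(unique(unlist(strsplit(d$variant_ids, ","))),
                          collapse = ","),
      n_sites = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cobel_set", "data.frame")
  out
}

#' @export
print.cobel_set <- function(x, ...) {
  s <- summarize_cobels(x)
  cat(sprintf("CoBEL set: %d loci (%d het, %d hom), %d factor(s)\n",
              s$total, s$het, s$hom, nrow(s$per_tf)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more loci\n")
  invisible(x)
}

#' Summary counts for a CoBEL set
#'
#' @param cobels a `cobel_set` (see [call_cobels()]).
#' @return list with `total`, `het`, `hom` counts and a `per_tf`
#'   data.frame (`tf`, `n`) whose counts sum to `total`.
#' @export
summarize_cobels <- function(cobels) {
  if (nrow(cobels) == 0) {
    return(list(total = 0L, het = 0L, hom = 0L,
                per_tf = data.frame(tf = character(), n = integer(),
                                    stringsAsFactors = FALSE)))
  }
  tab <- table(cobels$tf)
  list(total = nrow(cobels),
       het = sum(cobels$zygosity == "het"),
       hom = sum(cobels$zygosity == "hom"),
       per_tf = data.frame(tf = names(tab), n = as.integer(tab),
                           stringsAsFactors = FALSE))
}

#' Write a CoBEL set as BED6+
#'
#' BED columns: chrom, start, end, name (motif id), score
#' (`round(1000 * drop)`), strand; extra columns: tf, ancestral_score,
#' derived_score, drop, variant ids.
#'
#' @param cobels a `cobel_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cobels_bed <- function(cobels, path) {
  df <- data.frame(chrom = cobels$chrom, start = cobels$start,
                   end = cobels$end, name = cobels$motif_id,
                   score = round(1000 * cobels$drop), strand = cobels$strand,
                   tf = cobels$tf,
                   ancestral_score = sprintf("%.6f", cobels$ancestral_score),
                   derived_score = sprintf("%.6f", cobels$derived_score),
                   drop = sprintf("%.6f", cobels$drop),
                   variant_ids = cobels$variant_ids,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
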