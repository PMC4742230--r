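#' Configuration for a full screen run
#'
#' Collects the input paths, the per-stage configurations and the master
#' seed for one individual's screen. All paths must exist.
#'
#' @param genome,maf,tree,motifs,genes,chrom_sizes,variants,outgroup
#'   input file paths (FASTA, MAF, newick, motif TSV/MEME, gene TSV,
#'   chrom.sizes, VCF/pgSnp, outgroup TSV/FASTA).
#' @param ontology_edges,ontology_annotations,ontology_terms ontology
#'   TSV paths (`terms` optional).
#' @param ref_species reference species label used in the MAF and tree.
#' @param scan a [scan_config()].
#' @param call a [call_config()].
#' @param great a [great_config()].
#' @param n_control_shuffles matched-control sets for the null stage
#'   (default 10,000; the null stage runs only when [run_screen()] is
#'   asked to).
#' @param n_history_shuffles history shuffles for the association stage
#'   (default 1,000).
#' @param seed master seed; every stage derives its own stream from it.
#' @param output_dir where outputs are written.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genome, maf, tree, motifs, genes, chrom_sizes,
                       variants, outgroup, ontology_edges,
                       ontology_annotations, ontology_terms = NULL,
                       ref_species = "hg", scan = scan_config(),
                       call = call_config(), great = great_config(),
                       n_control_shuffles = 10000,
                       n_history_shuffles = 1000, seed = 1,
                       output_dir = tempfile("cobel_run")) {
  inputs <- c(genome = genome, maf = maf, tree = tree, motifs = motifs,
              genes = genes, chrom_sizes = chrom_sizes,
              variants = variants, outgroup = outgroup,
              ontology_edges = ontology_edges,
              ontology_annotations = ontology_annotations)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(genome = genome, maf = maf, tree = tree, motifs = motifs,
                 genes = genes, chrom_sizes = chrom_sizes,
                 variants = variants, outgroup = outgroup,
                 ontology_edges = ontology_edges,
                 ontology_annotations = ontology_annotations,
                 ontology_terms = ontology_terms,
                 ref_species = ref_species, scan = scan, call = call,
                 great = great, n_control_shuffles = n_control_shuffles,
                 n_history_shuffles = n_history_shuffles, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param manifest a `fixture_manifest` from [simulate_screen_inputs()].
#' @param ... overrides passed on to [run_config()].
#' @export
run_config_from_manifest <- function(manifest, ...) {
  p <- manifest$paths
  args <- list(genome = p$genome, maf = p$maf, tree = p$tree,
               motifs = p$motifs, genes = p$genes,
               chrom_sizes = p$chrom_sizes, variants = p$variants,
               outgroup = p$outgroup, ontology_edges = p$ontology_edges,
               ontology_annotations = p$ontology_annotations,
               ontology_terms = p$ontology_terms,
               ref_species = manifest$config$ref_species)
  do.call(run_config, modifyList(args, list(...)))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

run_header <- function(config) {
  sprintf("#cobelr %s config=%s seed=%d",
          as.character(utils::packageVersion("cobelr")),
          config_hash(config), config$seed)
}

read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Run the whole screen for one individual
#'
#' Stage order: scan the genome with the motif library, annotate and
#' filter for cross-species conservation, polarise and intersect the
#' individual's variants to call eroded loci, run the enrichment, and
#' optionally the matched-control null for the top term. Every output
#' file starts with a header line recording the package version, a hash
#' of the configuration and the seed; a rerun with an identical
#' configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @param do_nulls run the matched-control null stage for the top term
#'   (default `FALSE`; uses `config$n_control_shuffles` sets).
#' @param null_ancestor optional term id: when given, the null also
#'   reports the empirical p for the ancestor's related-term group.
#' @return a list of class `cobel_screen`: `sites` (conserved sites),
#'   `cobels`, `enrichment`, `top` (or `NULL`), `null` (or `NULL`),
#'   `paths` of the written outputs, and the `config`.
#' @export
run_screen <- function(config, do_nulls = FALSE, null_ancestor = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$output_dir, "screen.log")
  cat("", file = log_file)
  say <- function(...) cobel_log(..., file = log_file)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t1 <- Sys.time()
    val <- expr
    say(sprintf("stage %-10s done in %.1fs", name,
                as.numeric(Sys.time() - t1, units = "secs")))
    val
  }

  genome <- read_genome_fasta(config$genome)
  pwms <- read_motifs(config$motifs)
  blocks <- read_maf(config$maf, config$ref_species)
  tree <- read_phylo(config$tree, config$ref_species)
  genes <- read.table(config$genes, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  ont <- read_ontology_tsv(config$ontology_edges,
                           config$ontology_annotations,
                           config$ontology_terms)
  say(sprintf("inputs: %d chrom(s), %d motif(s), %d MAF block(s), %d gene(s), %d term(s)",
              length(genome), length(pwms), length(blocks), nrow(genes),
              nrow(ont$terms)))
  say(sprintf("thresholds: score_cutoff=%g min_species=%d min_branch_length=%g max_conservation_p=%g max_sites_per_motif=%d min_drop=%g max_q=%g min_fold=%g",
              config$scan$score_cutoff, config$scan$min_species,
              config$scan$min_branch_length,
              config$scan$max_conservation_p,
              config$scan$max_sites_per_motif, config$call$min_drop,
              config$great$max_q, config$great$min_fold))

  hits <- stage("scan", scan_genome(pwms, genome, config$scan$score_cutoff))
  say(sprintf("scan: %d raw hit(s)", nrow(hits)))
  annotated <- stage("conserve", annotate_conservation(
    hits, blocks, pwms, tree, config$scan, derive_seed(config$seed, 1000)))
  sites <- filter_conserved(annotated, config$scan)
  say(sprintf("conserve: %d conserved site(s)", nrow(sites)))

  variants <- stage("call", {
    v <- load_variants(config$variants, genome = genome)
    ancestral_filter(v, read_outgroup(config$outgroup))
  })
  cobels <- call_cobels(sites, variants, pwms, genome, config$call)
  say(sprintf("call: %d variant(s) after ancestral filter, %d CoBEL locus(i)",
              nrow(variants), nrow(cobels)))

  enrichment <- stage("enrich", great_enrichment(
    cobels, genes, chrom_sizes, ont, config$great))
  top <- rank_and_select_top(enrichment, config$great)
  say(if (is.null(top)) "enrich: no passing term"
      else sprintf("enrich: top term %s (binom_p=%.3g, fold=%.2f)",
                   top$term, top$binom_p, top$fold))

  null_res <- NULL
  if (do_nulls && !is.null(top) && nrow(cobels) > 0 &&
      config$n_control_shuffles > 0) {
    null_res <- stage("nulls", {
      cb <- attach_site_conservation(cobels, sites)
      pool <- build_control_pool(sites)
      exact <- matched_control_null(
        cb, pool, genes, chrom_sizes, ont, config$great,
        target_set = top$term,
        n_shuffles = config$n_control_shuffles,
        seed = derive_seed(config$seed, 2000))
      related <- NULL
      if (!is.null(null_ancestor)) {
        related <- empirical_top_term_p(
          top$term, exact$tops, related_term_group(ont, null_ancestor))
      }
      list(exact = exact$result, related = related, tops = exact$tops)
    })
    say(sprintf("nulls: exact-term empirical p = %.4g",
                null_res$exact$p))
  }

  header <- run_header(config)
  paths <- list(
    conserved = file.path(config$output_dir, "conserved_sites.bed"),
    cobels = file.path(config$output_dir, "cobels.bed"),
    enrichment = file.path(config$output_dir, "enrichment.tsv"),
    top = file.path(config$output_dir, "top_term.json"),
    log = log_file)
  writeLines(header, paths$conserved)
  write_table_append(write_conserved_frame(sites), paths$conserved)
  writeLines(header, paths$cobels)
  write_table_append(write_cobel_frame(cobels), paths$cobels)
  writeLines(header, paths$enrichment)
  write_table_append(as.data.frame(enrichment), paths$enrichment,
                     col.names = TRUE)
  jsonlite::write_json(
    list(header = header,
         top_term = if (is.null(top)) NA else top$term,
         top_name = if (is.null(top)) NA else top$name,
         n_cobels = nrow(cobels),
         binom_p = if (is.null(top)) NA else top$binom_p,
         binom_q = if (is.null(top)) NA else top$binom_q,
         fold = if (is.null(top)) NA else top$fold,
         null_exact_p = if (is.null(null_res)) NA else null_res$exact$p),
    paths$top, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("total %.1fs", as.numeric(Sys.time() - t0, units = "secs")))

  structure(list(sites = sites, cobels = cobels, enrichment = enrichment,
                 top = top, null = null_res, variants = variants,
                 paths = paths, config = config),
            class = "cobel_screen")
}

# data.frame renderings shared by the BED writers and run_screen
write_conserved_frame <- function(sites) {
  data.frame(sites$chrom, sites$start, sites$end, sites$motif_id,
             round(1000 * sites$score), sites$strand, sites$tf,
             sprintf("%.6f", sites$score), sites$n_species,
             sprintf("%.6f", sites$branch_length),
             sprintf("%.6g", sites$conservation_p),
             stringsAsFactors = FALSE)
}

write_cobel_frame <- function(cobels) {
  data.frame(cobels$chrom, cobels$start, cobels$end, cobels$motif_id,
             round(1000 * cobels$drop), cobels$strand, cobels$tf,
             sprintf("%.6f", cobels$ancestral_score),
             sprintf("%.6f", cobels$derived_score),
             sprintf("%.6f", cobels$drop), cobels$variant_ids,
             stringsAsFactors = FALSE)
}

write_table_append <- function(df, path, col.names = FALSE) {
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = col.names,
                               append = TRUE))
}

#' @export
print.cobel_screen <- function(x, ...) {
  cat("CoBEL screen\n")
  cat(sprintf("  conserved sites: %d\n", nrow(x$sites)))
  cat(sprintf("  CoBEL loci:      %d\n", nrow(x$cobels)))
  if (is.null(x$top)) {
    cat("  top term:        none passing the filters\n")
  } else {
    cat(sprintf("  top term:        %s (%s), k=%d, fold=%.2f, binom_q=%.3g\n",
                x$top$term, x$top$name, x$top$k, x$top$fold, x$top$binom_q))
  }
  if (!is.null(x$null)) {
    cat(sprintf("  null exact-term empirical p: %.4g (%d shuffles)\n",
                x$null$exact$p, x$null$exact$n_shuffles))
  }
  invisible(x)
}

#' Run a cohort of screens and tabulate top-term occurrence
#'
#' Applies [run_screen()] to each configuration, tracks every genome's
#' top enrichment, and computes the occurrence rate of a query term set
#' among them.
#'
#' @param configs list of [run_config()] objects.
#' @param target_set term ids whose occurrence rate is reported
#'   (optional).
#' @param output TSV path for the per-genome top-term table (optional).
#' @return list with `tops` (data.frame `genome`, `top_term`),
#'   `occurrence` (rate, or `NA` without a `target_set`).
#' @export
run_cohort <- function(configs, target_set = NULL, output = NULL) {
  stopifnot(length(configs) >= 1)
  tops <- vapply(seq_along(configs), function(i) {
    res <- run_screen(configs[[i]])
    if (is.null(res$top)) NA_character_ else res$top$term
  }, character(1))
  df <- data.frame(genome = seq_along(configs), top_term = tops,
                   stringsAsFactors = FALSE)
  if (!is.null(output)) {
    write.table(df, output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rate <- if (is.null(target_set)) NA_real_
          else occurrence_rate(target_set, tops)
  list(tops = df, occurrence = rate)
}
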