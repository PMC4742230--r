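#' GREAT-style enrichment configuration
#'
#' Default regulatory-domain geometry and significance filters: a basal
#' domain of 5,000 bases upstream and 1,000 bases downstream of each
#' gene's canonical TSS, extended up to the nearest neighbouring basal
#' domain or at most 1 Mb each side; a term is reported when both the
#' binomial (region) and hypergeometric (gene) FDR q-values are at most
#' 0.05 and the binomial fold enrichment is at least 2.
#'
#' @param basal_up,basal_down basal domain extent upstream/downstream of
#'   the TSS, bases (defaults 5000 / 1000).
#' @param max_extension maximum extension beyond the basal domain on each
#'   side, bases (default 1e6).
#' @param max_q FDR threshold applied to both tests (default 0.05).
#' @param min_fold minimum binomial fold enrichment (default 2).
#' @param attribution `"midpoint"` (default; a region belongs to every
#'   gene whose extended domain contains its midpoint) or `"any_overlap"`.
#' @return a list of class `great_config`.
#' @export
great_config <- function(basal_up = 5000, basal_down = 1000,
                         max_extension = 1e6, max_q = 0.05, min_fold = 2,
                         attribution = c("midpoint", "any_overlap")) {
  attribution <- match.arg(attribution)
  stopifnot(basal_up > 0, basal_down > 0, max_extension > 0,
            max_q > 0, min_fold > 0)
  structure(list(basal_up = basal_up, basal_down = basal_down,
                 max_extension = max_extension, max_q = max_q,
                 min_fold = min_fold, attribution = attribution),
            class = "great_config")
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain (`basal_up` bases upstream
#' and `basal_down` downstream of its TSS, half-open) and an extended
#' domain reaching to the nearest flanking basal-domain boundary of the
#' adjacent gene on each side, or `max_extension` bases beyond the basal
#' domain, whichever is closer; never less than the basal domain itself.
#' Domains are clipped at chromosome ends. Basal domains of different
#' genes may overlap.
#'
#' @param genes data.frame with columns `symbol`, `chrom`, `tss`
#'   (0-based), `strand`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param config a [great_config()].
#' @return data.frame with one row per gene: `symbol`, `chrom`, `tss`,
#'   `strand`, `basal_start`, `basal_end`, `start`, `end` (extended,
#'   0-based half-open).
#' @export
basal_plus_extension_domains <- function(genes, chrom_sizes,
                                         config = great_config()) {
  stopifnot(!anyDuplicated(genes$symbol))
  out <- list()
  for (chrom in unique(genes$chrom)) {
    size <- chrom_sizes[[chrom]]
    if (is.null(size)) stop("no chromosome size for ", chrom)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (any(g$tss < 0 | g$tss >= size)) {
      stop("gene TSS beyond chromosome end on ", chrom)
    }
    g <- g[order(g$tss), , drop = FALSE]
    up <- config$basal_up
    down <- config$basal_down
    basal_start <- ifelse(g$strand == "+", g$tss - up, g$tss - down + 1L)
    basal_end <- ifelse(g$strand == "+", g$tss + down, g$tss + up + 1L)
    basal_start <- pmax(0, basal_start)
    basal_end <- pmin(size, basal_end)
    n <- nrow(g)
    ext_start <- pmax(basal_start - config$max_extension, 0)
    ext_end <- pmin(basal_end + config$max_extension, size)
    if (n > 1) {
      left_nb <- c(NA, basal_end[-n])    # adjacent gene's basal boundary
      right_nb <- c(basal_start[-1], NA)
      ext_start <- ifelse(!is.na(left_nb),
                          pmax(ext_start, pmin(basal_start, left_nb)),
                          ext_start)
      ext_end <- ifelse(!is.na(right_nb),
                        pmin(ext_end, pmax(basal_end, right_nb)),
                        ext_end)
    }
    out[[chrom]] <- data.frame(symbol = g$symbol, chrom = chrom,
                               tss = g$tss, strand = g$strand,
                               basal_start = basal_start,
                               basal_end = basal_end,
                               start = ext_start, end = ext_end,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

domain_granges <- function(domains) {
  GenomicRanges::GRanges(domains$chrom,
                         IRanges::IRanges(domains$start + 1L, domains$end),
                         symbol = domains$symbol)
}

#' Genome fraction covered by a term's regulatory domains
#'
#' Length of the union of the extended regulatory domains of all genes
#' annotated (after propagation) to the term, divided by the genome size.
#' Overlapping domains are counted once.
#'
#' @param term term id.
#' @param ont an [ontology].
#' @param domains data.frame from [basal_plus_extension_domains()].
#' @param genome_size total assembled genome length (bases).
#' @return fraction in `[0, 1]`.
#' @export
term_genome_fraction <- function(term, ont, domains, genome_size) {
  if (!term %in% ont$terms$term) stop("unknown term: ", term)
  genes <- intersect(ont$genes[[term]], domains$symbol)
  if (!length(genes)) return(0)
  gr <- domain_granges(domains[domains$symbol %in% genes, , drop = FALSE])
  sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / genome_size
}

#' Binomial region-based enrichment test
#'
#' Upper-tail probability of observing at least `k` of `n` regions inside
#' a domain set covering fraction `p` of the genome, with the expected
#' count `n * p` and fold enrichment `k / (n * p)`.
#'
#' @param n total regions.
#' @param k regions inside the domain union.
#' @param p genome fraction covered by the domain union.
#' @return list with `p_value`, `fold`, `expected`. `p = 0` with `k > 0`
#'   gives p-value 0 and infinite fold (flagged via `degenerate = TRUE`).
#' @export
binomial_region_test <- function(n, k, p) {
  stopifnot(p >= 0, p <= 1, k >= 0, k <= n)
  expected <- n * p
  if (p == 0) {
    return(list(p_value = if (k > 0) 0 else 1,
                fold = if (k > 0) Inf else NA_real_,
                expected = 0, degenerate = k > 0))
  }
  p_value <- pbinom(k - 1, n, p, lower.tail = FALSE)
  list(p_value = p_value, fold = k / expected, expected = expected,
       degenerate = FALSE)
}

#' Hypergeometric gene-based enrichment test
#'
#' Upper-tail probability that at least `k_hit` of the `n_hit` genes with
#' at least one region are annotated, drawing without replacement from
#' `N` genes of which `K` are annotated.
#'
#' @param N total genes.
#' @param K annotated genes.
#' @param n_hit genes with at least one attributed region.
#' @param k_hit annotated genes among those.
#' @return upper-tail p-value.
#' @export
hypergeometric_gene_test <- function(N, K, n_hit, k_hit) {
  if (K > N || n_hit > N || k_hit > min(K, n_hit)) {
    stop("inconsistent hypergeometric counts")
  }
  phyper(k_hit - 1, K, N - K, n_hit, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1. Order-preserving
#' with the p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) p.adjust(p_values, method = "BH")

#' GREAT-style enrichment of a region set over an ontology
#'
#' For every ontology term with at least one annotated gene present in
#' the gene table, computes the binomial region test over the union of
#' the annotated genes' extended regulatory domains and the
#' hypergeometric gene test, with BH FDR within each ontology namespace.
#' Regions are attributed to genes by the configured rule (midpoint by
#' default).
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. a `cobel_set`.
#' @param genes gene table (`symbol`, `chrom`, `tss`, `strand`).
#' @param chrom_sizes named integer vector.
#' @param ont an [ontology].
#' @param config a [great_config()].
#' @param genome_size total genome size; defaults to `sum(chrom_sizes)`.
#' @return data.frame of class `great_results`, one row per tested term:
#'   `term`, `name`, `namespace`, `n`, `k`, `p`, `expected`, `fold`,
#'   `binom_p`, `binom_q`, `N_genes`, `K_annotated`, `n_hit_genes`,
#'   `k_hit_annotated`, `hyper_p`, `hyper_q`, `genes_hit`.
#' @export
great_enrichment <- function(regions, genes, chrom_sizes, ont,
                             config = great_config(),
                             genome_size = sum(chrom_sizes)) {
  domains <- basal_plus_extension_domains(genes, chrom_sizes, config)
  dom_gr <- domain_granges(domains)
  n <- nrow(regions)
  if (n > 0) {
    if (config$attribution == "midpoint") {
      mid <- floor((regions$start + regions$end) / 2)
      reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                       IRanges::IRanges(mid + 1L, mid + 1L))
    } else {
      reg_gr <- GenomicRanges::GRanges(
        regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
    }
    ov <- GenomicRanges::findOverlaps(reg_gr, dom_gr, ignore.strand = TRUE)
    hit_gene_of_region <- split(domains$symbol[S4Vectors::subjectHits(ov)],
                                S4Vectors::queryHits(ov))
  } else {
    hit_gene_of_region <- list()
  }
  genes_with_hit <- unique(unlist(hit_gene_of_region))
  region_genes <- lapply(seq_len(n), function(i)
    hit_gene_of_region[[as.character(i)]] %||% character(0))
  N_genes <- nrow(genes)
  rows <- list()
  for (t in ont$terms$term) {
    ann <- intersect(ont$genes[[t]], genes$symbol)
    if (!length(ann)) next
    frac <- term_genome_fraction(t, ont, domains, genome_size)
    k <- if (n > 0) sum(vapply(region_genes,
                               function(g) any(g %in% ann), logical(1)))
         else 0L
    bin <- binomial_region_test(n, k, frac)
    n_hit <- length(genes_with_hit)
    k_hit <- length(intersect(genes_with_hit, ann))
    hyper_p <- hypergeometric_gene_test(N_genes, length(ann), n_hit, k_hit)
    meta <- ont$terms[ont$terms$term == t, ]
    rows[[t]] <- data.frame(
      term = t, name = meta$name, namespace = meta$namespace,
      n = n, k = k, p = frac, expected = bin$expected, fold = bin$fold,
      binom_p = bin$p_value, N_genes = N_genes, K_annotated = length(ann),
      n_hit_genes = n_hit, k_hit_annotated = k_hit, hyper_p = hyper_p,
      genes_hit = paste(sort(intersect(genes_with_hit, ann)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(term = character(), name = character(),
                      namespace = character(), n = integer(), k = integer(),
                      p = numeric(), expected = numeric(), fold = numeric(),
                      binom_p = numeric(), binom_q = numeric(),
                      N_genes = integer(), K_annotated = integer(),
                      n_hit_genes = integer(), k_hit_annotated = integer(),
                      hyper_p = numeric(), hyper_q = numeric(),
                      genes_hit = character(), stringsAsFactors = FALSE)
    class(res) <- c("great_results", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$binom_q <- NA_real_
  res$hyper_q <- NA_real_
  for (ns in unique(res$namespace)) {
    idx <- res$namespace == ns
    res$binom_q[idx] <- bh_fdr(res$binom_p[idx])
    res$hyper_q[idx] <- bh_fdr(res$hyper_p[idx])
  }
  res <- res[, c("term", "name", "namespace", "n", "k", "p", "expected",
                 "fold", "binom_p", "binom_q", "N_genes", "K_annotated",
                 "n_hit_genes", "k_hit_annotated", "hyper_p", "hyper_q",
                 "genes_hit")]
  res <- res[order(res$binom_p, -res$fold, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("great_results", "data.frame")
  res
}

#' @export
print.great_results <- function(x, ...) {
  cat(sprintf("GREAT-style enrichment: %d tested term(s)\n", nrow(x)))
  cols <- c("term", "name", "k", "expected", "fold", "binom_p", "binom_q",
            "hyper_q")
  if (nrow(x)) print.data.frame(head(as.data.frame(x)[, cols], 10),
                                digits = 4)
  invisible(x)
}

#' Top enrichment under the default filters
#'
#' Candidates must satisfy `binom_q <= max_q`, `hyper_q <= max_q` and
#' `fold >= min_fold`; the top term is the candidate with the smallest
#' binomial p-value (ties: larger fold, then lexicographic term id).
#'
#' @param results a `great_results` data.frame.
#' @param config a [great_config()].
#' @return one-row data.frame, or `NULL` when no term passes.
#' @export
rank_and_select_top <- function(results, config = great_config()) {
  ok <- !is.na(results$binom_q) & results$binom_q <= config$max_q &
    !is.na(results$hyper_q) & results$hyper_q <= config$max_q &
    !is.na(results$fold) & results$fold >= config$min_fold
  cand <- results[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$binom_p, -cand$fold, cand$term), , drop = FALSE]
  out <- as.data.frame(cand[1, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' @param results a `great_results` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
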