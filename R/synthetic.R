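#' Configuration for the synthetic screen fixture
#'
#' Describes a toy study in which a reference genome carries planted,
#' perfectly conserved binding sites near genes annotated to a chosen
#' ontology term, and an individual's variant file erodes a fraction of
#' them. All randomness flows from the single master `seed`;
#' per-component seeds are derived by fixed offsets recorded in the
#' manifest.
#'
#' @param n_species number of non-reference aligned species (default 8).
#' @param genome_length reference length in bases (default 500,000; must
#'   allow `8000` bases of room per gene).
#' @param n_genes number of genes (default 60).
#' @param n_terms ontology terms incl. root and the target's parent
#'   (default 12).
#' @param target_term id of the term whose genes receive planted sites
#'   (default `"T_target"`).
#' @param n_target_genes genes annotated to the target term (default 8).
#' @param n_planted_sites_per_target_gene planted target-motif sites in
#'   each target gene's basal domain (default 5).
#' @param n_decoy_sites_per_gene planted target-motif sites in each
#'   non-target gene's basal domain, populating the matched-control pool
#'   away from the target genes (default 2).
#' @param erosion_fraction fraction of target-gene planted sites given an
#'   eroding derived variant (default 0.8).
#' @param background_snv_rate per-base probability of a background SNV
#'   (default 1e-4).
#' @param substitution_rate_scale per-branch background divergence
#'   multiplier: a branch of length b mutates each background column with
#'   probability `min(0.75, b * scale)` (default 1).
#' @param n_motifs motif library size incl. the target motif (default 6).
#' @param motif_length motif length in bases (default 8).
#' @param block_size MAF block size in bases (default 1000).
#' @param chrom,ref_species chromosome and reference species labels.
#' @param seed master seed.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(n_species = 8, genome_length = 500000,
                           n_genes = 60, n_terms = 12,
                           target_term = "T_target", n_target_genes = 8,
                           n_planted_sites_per_target_gene = 5,
                           n_decoy_sites_per_gene = 2,
                           erosion_fraction = 0.8,
                           background_snv_rate = 1e-4,
                           substitution_rate_scale = 1,
                           n_motifs = 6, motif_length = 8,
                           block_size = 1000, chrom = "chr1",
                           ref_species = "hg", seed = 1) {
  stopifnot(n_species >= 2, erosion_fraction >= 0, erosion_fraction <= 1,
            n_terms >= 3, n_motifs >= 1, motif_length >= 4,
            n_target_genes < n_genes,
            genome_length >= 8000 * n_genes)
  structure(as.list(environment()), class = "fixture_config")
}

#' Simulate a random neutral phylogeny for the fixture
#'
#' Random bifurcating topology over `sp1..spN` with branch lengths drawn
#' uniformly from 0.05-0.5 substitutions/site; the reference species is
#' attached at the root with a 0-length pendant branch. If the total tree
#' length falls below `min_total` it is rescaled up, so a fully preserved
#' site always clears the 2 substitutions/site conservation filter.
#'
#' @param n_species number of non-reference species.
#' @param seed integer seed.
#' @param ref_species reference tip label.
#' @param min_total minimum total branch length (default 2).
#' @return an [ape::phylo] with `ref_species` attribute.
#' @export
simulate_tree <- function(n_species, seed, ref_species = "hg",
                          min_total = 2) {
  tree <- with_seed(seed, {
    tr <- ape::rtree(n_species, tip.label = paste0("sp", seq_len(n_species)))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
    tr
  })
  total <- sum(tree$edge.length)
  if (total < min_total) {
    # overshoot a hair so the bound survives floating-point round-trips
    tree$edge.length <- tree$edge.length * min_total * (1 + 1e-9) / total
  }
  base <- sub(";\\s*$", "", ape::write.tree(tree))
  full <- ape::read.tree(text = sprintf("(%s:0,%s:0);", base, ref_species))
  validate_phylo(full, ref_species)
}

# A sharp random motif: consensus base 1 - 3*eps, others eps. Sampled so
# that all four bases occur when length allows, keeping shuffles
# distinguishable from the original.
random_sharp_pwm <- function(id, tf, L, eps = 0.03) {
  cons <- sample(DNA_BASES, L, replace = TRUE)
  if (L >= 4) cons[1:4] <- sample(DNA_BASES)  # guarantee base diversity
  freqs <- matrix(eps, 4, L, dimnames = list(DNA_BASES, NULL))
  freqs[cbind(match(cons, DNA_BASES), seq_len(L))] <- 1 - 3 * eps
  pwm(freqs, id = id, tf_name = tf, pseudocount = 0)
}

mutate_codes <- function(codes, p) {
  idx <- which(runif(length(codes)) < p)
  if (length(idx)) {
    codes[idx] <- ((codes[idx] - 1L +
                      sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  }
  codes
}

# Evolve the reference down the tree; returns a matrix species x bases
# (integer codes). Planted columns are restored to the reference
# afterwards by the caller.
evolve_alignment <- function(ref_codes, tree, ref_species, rate_scale) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- ref_codes
  pre <- ape::reorder.phylo(tree, "cladewise")   # parent before child
  for (e in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[e, 1]
    child <- pre$edge[e, 2]
    p_mut <- min(0.75, pre$edge.length[e] * rate_scale)
    seqs[[child]] <- mutate_codes(seqs[[parent]], p_mut)
  }
  tips <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(tips) <- tree$tip.label
  tips[ref_species, ] <- ref_codes   # 0-length pendant branch
  tips
}

#' Generate the complete synthetic screen fixture
#'
#' Writes every input the pipeline consumes — reference FASTA, MAF
#' alignment, newick tree, motif TSV, gene TSV, chrom.sizes, ontology
#' TSVs, individual VCF, outgroup TSV — plus a planted-truth BED and a
#' JSON manifest, into `dir`. Planted sites are exact target-motif
#' consensus occurrences, copied unchanged to every aligned species
#' (perfectly conserved), placed inside gene basal domains and never
#' across MAF block boundaries. A fraction `erosion_fraction` of the
#' target-gene sites receives a derived SNV at the site's
#' maximum-information position, replacing the consensus base with the
#' motif's least-frequent base (a guaranteed >5\% affinity drop); the
#' outgroup base equals the reference at every variant position, so all
#' variants pass the ancestral filter.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return a list of class `fixture_manifest`: file `paths`, the
#'   `config`, the planted `truth` table, and derived seeds.
#' @export
simulate_screen_inputs <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  chrom <- cfg$chrom
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    maf = file.path(dir, "alignment.maf"),
    tree = file.path(dir, "tree.nwk"),
    motifs = file.path(dir, "motifs.tsv"),
    genes = file.path(dir, "genes.tsv"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    ontology_terms = file.path(dir, "ontology_terms.tsv"),
    ontology_edges = file.path(dir, "ontology_edges.tsv"),
    ontology_annotations = file.path(dir, "ontology_annotations.tsv"),
    variants = file.path(dir, "individual.vcf"),
    outgroup = file.path(dir, "outgroup.tsv"),
    truth = file.path(dir, "planted_truth.bed"),
    manifest = file.path(dir, "manifest.json"))
  seeds <- list(tree = derive_seed(cfg$seed, 1), motifs = derive_seed(cfg$seed, 2),
                genome = derive_seed(cfg$seed, 3), placement = derive_seed(cfg$seed, 4),
                alignment = derive_seed(cfg$seed, 5), individual = derive_seed(cfg$seed, 6))

  ## tree
  tree <- simulate_tree(cfg$n_species, seeds$tree, cfg$ref_species)
  ape::write.tree(tree, paths$tree)

  ## motif library: one target motif + decoys
  pwms <- with_seed(seeds$motifs, {
    out <- list(M_target = random_sharp_pwm("M_target", "TF_target",
                                            cfg$motif_length))
    for (i in seq_len(cfg$n_motifs - 1)) {
      id <- sprintf("M_dec%02d", i)
      out[[id]] <- random_sharp_pwm(id, sprintf("TF_dec%02d", i),
                                    cfg$motif_length)
    }
    out
  })
  write_motifs_tsv(pwms, paths$motifs)

  ## genes, evenly spaced, alternating strands
  spacing <- floor(cfg$genome_length / cfg$n_genes)
  genes <- data.frame(
    symbol = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = chrom,
    tss = spacing * (seq_len(cfg$n_genes) - 1L) + floor(spacing / 2),
    strand = rep(c("+", "-"), length.out = cfg$n_genes),
    stringsAsFactors = FALSE)
  target_idx <- unique(round(seq(2, cfg$n_genes - 1,
                                 length.out = cfg$n_target_genes)))
  target_genes <- genes$symbol[target_idx]
  write.table(genes, paths$genes, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", chrom, cfg$genome_length), paths$chrom_sizes)

  ## ontology: root -> {parent, decoys}; parent -> target
  root <- "T_root"
  parent <- "T_parent"
  decoys <- sprintf("T_dec%02d", seq_len(cfg$n_terms - 3))
  terms <- data.frame(term = c(root, parent, cfg$target_term, decoys),
                      name = c("toy root", "parent of target term",
                               "planted target term",
                               sprintf("decoy term %d", seq_along(decoys))),
                      namespace = "toy", stringsAsFactors = FALSE)
  edges <- rbind(data.frame(child = parent, parent = root),
                 data.frame(child = cfg$target_term, parent = parent),
                 data.frame(child = decoys, parent = root))
  other <- setdiff(genes$symbol, target_genes)
  # two direct parent annotations keep the parent term strictly broader
  # than the target, so ties resolve to the planted term
  annotations <- rbind(
    data.frame(gene = target_genes, term = cfg$target_term),
    data.frame(gene = other[1:2], term = parent),
    data.frame(gene = other, term = rep(decoys, length.out = length(other))))
  write.table(terms, paths$ontology_terms, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, paths$ontology_edges, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(annotations, paths$ontology_annotations, sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## reference genome
  ref_codes <- with_seed(seeds$genome,
                         sample.int(4L, cfg$genome_length, replace = TRUE))

  ## planted sites: target-motif consensus in basal domains
  L <- cfg$motif_length
  target_pwm <- pwms$M_target
  cons_codes <- match(strsplit(consensus(target_pwm), "")[[1]], DNA_BASES)
  snap_to_block <- function(pos) {
    pos <- pmax(0L, pmin(as.integer(pos), cfg$genome_length - L))
    # keep [pos, pos+L) inside one MAF block
    over <- (pos %% cfg$block_size) > cfg$block_size - L
    pos[over] <- pos[over] - L
    pos
  }
  site_positions <- function(g_row, n_sites) {
    # offsets inside the strand-aware basal domain, close enough to the
    # TSS that no neighbouring gene's basal domain can also cover them
    if (genes$strand[g_row] == "+") {
      from <- genes$tss[g_row] - 3000
    } else {
      from <- genes$tss[g_row] - 600
    }
    snap_to_block(from + 600 * (seq_len(n_sites) - 1L))
  }
  truth <- list()
  for (gi in seq_len(cfg$n_genes)) {
    is_target <- gi %in% target_idx
    n_sites <- if (is_target) cfg$n_planted_sites_per_target_gene
               else cfg$n_decoy_sites_per_gene
    if (n_sites == 0) next
    for (pos in site_positions(gi, n_sites)) {
      ref_codes[(pos + 1L):(pos + L)] <- cons_codes
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + L, motif_id = "M_target",
        strand = "+", gene = genes$symbol[gi],
        target_gene = is_target, stringsAsFactors = FALSE)
    }
  }
  ## one decoy-motif site at every third gene for background diversity
  decoy_pwms <- pwms[names(pwms) != "M_target"]
  if (length(decoy_pwms)) {
    for (gi in seq(1, cfg$n_genes, by = 3)) {
      dp <- decoy_pwms[[1L + (gi %% length(decoy_pwms))]]
      pos <- snap_to_block(genes$tss[gi] + 1500)
      dcons <- match(strsplit(consensus(dp), "")[[1]], DNA_BASES)
      ref_codes[(pos + 1L):(pos + L)] <- dcons
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + L, motif_id = dp$id,
        strand = "+", gene = genes$symbol[gi], target_gene = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  genome <- setNames(decode_dna(ref_codes), chrom)
  write_genome_fasta(genome, paths$genome)

  ## alignment: evolve background, restore planted columns everywhere
  tips <- with_seed(seeds$alignment,
                    evolve_alignment(ref_codes, tree, cfg$ref_species,
                                     cfg$substitution_rate_scale))
  planted_cols <- unlist(lapply(seq_len(nrow(truth)), function(i)
    (truth$start[i] + 1L):truth$end[i]))
  tips[, planted_cols] <- rep(ref_codes[planted_cols],
                              each = nrow(tips))
  species_order <- c(cfg$ref_species,
                     setdiff(tree$tip.label, cfg$ref_species))
  blocks <- list()
  for (bs in seq(0, cfg$genome_length - 1, by = cfg$block_size)) {
    be <- min(bs + cfg$block_size, cfg$genome_length)
    blocks[[length(blocks) + 1L]] <- list(
      chrom = chrom, start = bs, end = be,
      species = species_order,
      seqs = vapply(species_order, function(sp)
        decode_dna(tips[sp, (bs + 1L):be]), character(1)))
  }
  blocks <- structure(blocks, class = "maf_alignment",
                      ref_species = cfg$ref_species)
  write_maf(blocks, paths$maf, setNames(cfg$genome_length, chrom))

  ## individual: eroding SNVs at planted target-gene sites + background
  iv <- information_vector(target_pwm)
  erode_off <- which.max(iv) - 1L
  erode_from <- cons_codes[erode_off + 1L]
  erode_to <- match(strsplit(anti_consensus(target_pwm), "")[[1]][erode_off + 1L],
                    DNA_BASES)
  target_rows <- which(truth$target_gene)
  variants <- with_seed(seeds$individual, {
    n_erode <- round(cfg$erosion_fraction * length(target_rows))
    eroded_rows <- if (n_erode > 0) sort(sample(target_rows, n_erode))
                   else integer(0)
    v <- list()
    for (r in eroded_rows) {
      pos <- truth$start[r] + erode_off
      v[[length(v) + 1L]] <- data.frame(
        pos = pos, ref = DNA_BASES[erode_from], alt = DNA_BASES[erode_to],
        zygosity = sample(c("het", "hom"), 1), stringsAsFactors = FALSE)
    }
    footprint <- unique(planted_cols)
    n_bg <- rbinom(1, cfg$genome_length, cfg$background_snv_rate)
    bg_pos <- setdiff(sample.int(cfg$genome_length, n_bg) - 1L, footprint - 1L)
    for (pos in bg_pos) {
      ref_b <- ref_codes[pos + 1L]
      v[[length(v) + 1L]] <- data.frame(
        pos = pos, ref = DNA_BASES[ref_b],
        alt = DNA_BASES[((ref_b - 1L + sample.int(3L, 1)) %% 4L) + 1L],
        zygosity = sample(c("het", "hom"), 1), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, v)
    if (is.null(df)) {
      df <- data.frame(pos = integer(), ref = character(),
                       alt = character(), zygosity = character())
    }
    df$eroding <- c(rep(TRUE, length(eroded_rows)),
                    rep(FALSE, nrow(df) - length(eroded_rows)))
    attr(df, "eroded_rows") <- eroded_rows
    df
  })
  eroded_rows <- attr(variants, "eroded_rows")
  truth$eroded <- seq_len(nrow(truth)) %in% eroded_rows
  variants <- variants[order(variants$pos), , drop = FALSE]

  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, cfg$genome_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tINDIV"))
  if (nrow(variants)) {
    vcf_lines <- c(vcf_lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
      chrom, variants$pos + 1L, variants$ref, variants$alt,
      ifelse(variants$zygosity == "hom", "1/1", "0/1")))
  }
  writeLines(vcf_lines, paths$variants)
  write.table(data.frame(chrom = rep(chrom, nrow(variants)),
                         pos = variants$pos, base = variants$ref),
              paths$outgroup, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  ## planted-truth BED6+ (extras: gene, target_gene, eroded)
  write.table(data.frame(truth$chrom, truth$start, truth$end,
                         truth$motif_id, 1000L, truth$strand, truth$gene,
                         as.integer(truth$target_gene),
                         as.integer(truth$eroded)),
              paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  manifest <- structure(list(paths = paths, config = unclass(cfg),
                             seeds = seeds, target_genes = target_genes,
                             truth = truth),
                        class = "fixture_manifest")
  jsonlite::write_json(
    list(paths = lapply(paths, normalizePath, mustWork = FALSE),
         config = unclass(cfg), seeds = seeds,
         target_genes = target_genes),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "Synthetic screen fixture: %d bp genome, %d genes, %d planted sites (%d eroded)\n",
    x$config$genome_length, x$config$n_genes, nrow(x$truth),
    sum(x$truth$eroded)))
  cat("Files in:", dirname(x$paths$genome), "\n")
  invisible(x)
}

#' Build a toy ontology in memory
#'
#' The in-memory counterpart of the ontology files written by
#' [simulate_screen_inputs()]: a root, a parent of the target term, the
#' target term and decoy terms, with the given gene annotations.
#' Convenience for tests and examples.
#'
#' @param target_term target term id.
#' @param target_genes genes annotated to the target term.
#' @param other_genes remaining genes (first two also annotate the
#'   parent term directly).
#' @param n_terms total number of terms (>= 3).
#' @return an [ontology].
#' @export
make_toy_ontology <- function(target_term, target_genes, other_genes,
                              n_terms = 12) {
  stopifnot(n_terms >= 3)
  root <- "T_root"
  parent <- "T_parent"
  decoys <- sprintf("T_dec%02d", seq_len(n_terms - 3))
  terms <- data.frame(term = c(root, parent, target_term, decoys),
                      name = c(root, parent, target_term, decoys),
                      namespace = "toy", stringsAsFactors = FALSE)
  edges <- rbind(data.frame(child = parent, parent = root),
                 data.frame(child = target_term, parent = parent),
                 data.frame(child = decoys, parent = root))
  annotations <- rbind(
    data.frame(gene = target_genes, term = target_term),
    if (length(other_genes) >= 2)
      data.frame(gene = other_genes[1:2], term = parent),
    if (length(other_genes))
      data.frame(gene = other_genes,
                 term = rep(decoys, length.out = length(other_genes))))
  ontology(terms, edges, annotations)
}
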