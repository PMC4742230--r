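# Shared toy fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small, fast fixture for unit and pipeline tests (a few seconds to
# simulate and screen).
small_fixture_config <- function(seed = 42, background_snv_rate = 5e-5,
                                 ...) {
  fixture_config(n_species = 6, genome_length = 100000, n_genes = 12,
                 n_terms = 6, n_target_genes = 4,
                 n_planted_sites_per_target_gene = 4,
                 n_decoy_sites_per_gene = 2, n_motifs = 3,
                 background_snv_rate = background_snv_rate,
                 seed = seed, ...)
}

get_fixture <- function(key, config) {
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("cobelr_fix_", key))
    .fixture_cache[[key]] <- simulate_screen_inputs(config, dir)
  }
  .fixture_cache[[key]]
}

get_small_screen <- function() {
  if (is.null(.fixture_cache$small_screen)) {
    man <- get_fixture("small42", small_fixture_config())
    rc <- run_config_from_manifest(
      man, seed = 42, output_dir = file.path(tempdir(), "cobelr_run_small"))
    .fixture_cache$small_screen <- suppressMessages(run_screen(rc))
  }
  .fixture_cache$small_screen
}

# A 6-species toy alignment block with planted consensus columns; used by
# the conservation tests. Returns list(block, tree, pwm, site).
toy_conserved_block <- function(seed = 1, block_len = 800, n_species = 6,
                                planted_at = 300) {
  set.seed(seed)
  p <- random_sharp_toy_pwm(8)
  cons <- consensus(p)
  L <- nchar(cons)
  ref <- paste(sample(c("A", "C", "G", "T"), block_len, replace = TRUE),
               collapse = "")
  substr(ref, planted_at + 1, planted_at + L) <- cons
  rows <- c(ref, vapply(seq_len(n_species), function(i) {
    chars <- sample(c("A", "C", "G", "T"), block_len, replace = TRUE)
    paste(chars, collapse = "")
  }, character(1)))
  for (i in 2:(n_species + 1)) {
    substr(rows[i], planted_at + 1, planted_at + L) <- cons
  }
  species <- c("hg", paste0("sp", seq_len(n_species)))
  block <- list(chrom = "chr1", start = 0L, end = block_len,
                species = species, seqs = rows)
  tree <- ape::read.tree(text = paste0(
    "(", paste(sprintf("sp%d:0.4", seq_len(n_species)), collapse = ","),
    ",hg:0);"))
  attr(tree, "ref_species") <- "hg"
  site <- list(chrom = "chr1", start = planted_at,
               end = planted_at + L, strand = "+")
  list(block = block, tree = tree, pwm = p, site = site)
}

# sharp PWM without reaching into package internals
random_sharp_toy_pwm <- function(L, eps = 0.03) {
  cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cons[1:4] <- sample(c("A", "C", "G", "T"))
  m <- matrix(eps, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(cons, c("A", "C", "G", "T")), seq_len(L))] <- 1 - 3 * eps
  pwm(m, id = "toy", pseudocount = 0)
}
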