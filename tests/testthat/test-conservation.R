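test_that("preserved branch length sums the induced subtree", {
  # reference R attached at the root with a 0-length branch
  tree <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1.0,R:0);")
  attr(tree, "ref_species") <- "R"
  expect_equal(preserved_branch_length(character(0), tree), 0)
  expect_equal(preserved_branch_length(c("A", "B"), tree), 1.5)
  expect_equal(preserved_branch_length(c("A", "B", "C"), tree), 2.5)
  expect_error(preserved_branch_length("nope", tree), "not in tree")
})

test_that("preserved branch length is monotone under adding species", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    tree <- ape::rtree(n, tip.label = paste0("s", 1:n))
    tree$edge.length <- runif(nrow(tree$edge), 0.01, 1)
    attr(tree, "ref_species") <- "s1"
    others <- sample(paste0("s", 2:n))
    prev <- 0
    for (k in seq_along(others)) {
      cur <- preserved_branch_length(others[1:k], tree)
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  }
})

test_that("reference scanning finds exactly the planted/brute-forced hits", {
  set.seed(21)
  p <- random_sharp_toy_pwm(8)
  L <- 8
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  genome <- c(chrA = bg)
  substr(genome["chrA"], 501, 500 + L) <- consensus(p)
  hits <- scan_reference(p, genome, 0.95)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == 500))
  expect_true(all(hits$score >= 0.95))

  # cutoff 0 reports every window on both strands
  all_hits <- scan_reference(p, c(s = substr(bg, 1, 100)), 0)
  expect_equal(nrow(all_hits), 2 * (100 - L + 1))

  # brute force re-scoring agreement at cutoff 0.9
  brute <- list()
  seqc <- strsplit(genome[["chrA"]], "")[[1]]
  rc <- reverse_complement_pwm(p)
  for (j in seq_len(2000 - L + 1)) {
    w <- paste(seqc[j:(j + L - 1)], collapse = "")
    for (str in c("+", "-")) {
      s <- match_score(if (str == "+") p else rc, w)
      if (s >= 0.9) {
        brute[[length(brute) + 1L]] <- data.frame(start = j - 1L,
                                                  strand = str, score = s)
      }
    }
  }
  brute <- do.call(rbind, brute)
  got <- scan_reference(p, genome, 0.9)
  expect_equal(nrow(got), nrow(brute))
  expect_equal(got[order(got$start, got$strand), c("start", "strand", "score")],
               brute[order(brute$start, brute$strand), ],
               ignore_attr = TRUE)
})

test_that("species preservation follows the gap and score rules", {
  toy <- toy_conserved_block(seed = 30)
  # all species carry the planted consensus
  sp <- species_preserving_site(toy$site, toy$block, toy$pwm, 0.9)
  expect_setequal(sp, paste0("sp", 1:6))

  # destroy the site in two species; one more gets a gap
  blk <- toy$block
  substr(blk$seqs[2], toy$site$start + 1, toy$site$end) <-
    substr(anti_consensus(toy$pwm), 1, 8)
  substr(blk$seqs[3], toy$site$start + 1, toy$site$end) <-
    substr(anti_consensus(toy$pwm), 1, 8)
  substr(blk$seqs[4], toy$site$start + 3, toy$site$start + 3) <- "-"
  sp <- species_preserving_site(toy$site, blk, toy$pwm, 0.9)
  expect_setequal(sp, c("sp4", "sp5", "sp6"))

  expect_error(
    species_preserving_site(list(chrom = "chr1", start = 795, end = 803,
                                 strand = "+"), blk, toy$pwm, 0.9),
    "outside")
})

test_that("conservation p-value behaves at its boundary cases", {
  toy <- toy_conserved_block(seed = 31)
  cfg <- scan_config(n_shuffles_for_p = 19, score_cutoff = 0.9)

  # a site preserved in zero species scores p = 1
  blk <- toy$block
  for (i in 2:7) {
    substr(blk$seqs[i], toy$site$start + 1, toy$site$end) <-
      substr(anti_consensus(toy$pwm), 1, 8)
  }
  p0 <- conservation_pvalue(c(toy$site, branch_length = 0), toy$pwm, blk,
                            toy$tree, cfg, seed = 1)
  expect_equal(p0, 1)

  # single-column motif: shuffling is the identity, p = 1
  p1col <- pwm(matrix(c(0.91, 0.03, 0.03, 0.03), 4, 1), "c1",
               pseudocount = 0)
  blk1 <- toy$block
  site1 <- list(chrom = "chr1", start = toy$site$start,
                end = toy$site$start + 1L, strand = "+")
  p1 <- conservation_pvalue(site1, p1col, blk1, toy$tree, cfg, seed = 2)
  expect_equal(p1, 1)
})

test_that("a planted deeply conserved site is usually significant", {
  cfg <- scan_config(n_shuffles_for_p = 99, score_cutoff = 0.9)
  n_sig <- 0
  n_seeds <- 40
  for (seed in seq_len(n_seeds)) {
    toy <- toy_conserved_block(seed = 100 + seed)
    site <- toy$site
    site$branch_length <- preserved_branch_length(
      species_preserving_site(site, toy$block, toy$pwm, 0.9), toy$tree)
    p <- conservation_pvalue(site, toy$pwm, toy$block, toy$tree, cfg,
                             seed = seed)
    if (p <= 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / n_seeds, 0.9)
})

test_that("conservation filtering applies thresholds, ranking and the cap", {
  mk <- function(n, motif = "m", p = 0.01, score = 0.95, ns = 6, bl = 2.5) {
    data.frame(chrom = "chr1", start = seq_len(n) * 10,
               end = seq_len(n) * 10 + 8, strand = "+", motif_id = motif,
               tf = motif, score = score, n_species = ns,
               branch_length = bl, conservation_p = p,
               stringsAsFactors = FALSE)
  }
  cfg <- scan_config(max_sites_per_motif = 5)

  expect_equal(nrow(filter_conserved(mk(1, ns = 4), cfg)), 0)
  expect_equal(nrow(filter_conserved(mk(1, bl = 1.9), cfg)), 0)
  expect_equal(nrow(filter_conserved(mk(1, p = 0.06), cfg)), 0)

  # cap: 8 qualifying hits, cap 5, the retained rank above the discarded
  hits <- mk(8)
  hits$conservation_p <- c(.01, .02, .03, .04, .05, .049, .001, .02)
  kept <- filter_conserved(hits, cfg)
  expect_equal(nrow(kept), 5)
  expect_true(max(kept$conservation_p) <=
                min(setdiff(hits$conservation_p, kept$conservation_p)))

  # brute-force agreement on a mixed set of 10
  set.seed(33)
  mixed <- mk(10)
  mixed$n_species <- sample(3:8, 10, replace = TRUE)
  mixed$branch_length <- runif(10, 1, 3)
  mixed$conservation_p <- runif(10, 0, 0.1)
  expected <- mixed[mixed$n_species >= 5 & mixed$branch_length >= 2 &
                      mixed$conservation_p <= 0.05, ]
  got <- filter_conserved(mixed, scan_config())
  expect_setequal(got$start, expected$start)

  # idempotence
  expect_equal(filter_conserved(got, scan_config()), got)
})

test_that("MAF round-trips through write and read", {
  toy <- toy_conserved_block(seed = 40)
  blocks <- structure(list(toy$block), class = "maf_alignment",
                      ref_species = "hg")
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, path, c(chr1 = 800L))
  back <- read_maf(path, "hg")
  expect_length(back, 1)
  expect_equal(back[[1]]$chrom, "chr1")
  expect_equal(back[[1]]$start, 0L)
  expect_equal(back[[1]]$end, 800L)
  expect_equal(back[[1]]$species, toy$block$species)
  expect_equal(back[[1]]$seqs, toy$block$seqs)
})

test_that("conserved sites re-score to their stored match score", {
  scr <- get_small_screen()
  man <- get_fixture("small42", small_fixture_config())
  genome <- read_genome_fasta(man$paths$genome)
  pwms <- read_motifs(man$paths$motifs)
  sites <- scr$sites
  for (i in seq_len(min(nrow(sites), 25))) {
    w <- substr(genome[[sites$chrom[i]]], sites$start[i] + 1, sites$end[i])
    p <- pwms[[sites$motif_id[i]]]
    if (sites$strand[i] == "-") p <- reverse_complement_pwm(p)
    expect_equal(match_score(p, w), sites$score[i], tolerance = 1e-9)
  }
})
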