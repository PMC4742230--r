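mk_sites <- function(n, motif = "m1", score = 0.95, p = 0.01,
                     start = seq_len(n) * 100) {
  data.frame(chrom = "chr1", start = start, end = start + 8, strand = "+",
             motif_id = motif, tf = motif, score = score, n_species = 6,
             branch_length = 2.5, conservation_p = p,
             stringsAsFactors = FALSE)
}

test_that("control pool buckets partition sites by motif, affinity, p-decade", {
  s <- rbind(mk_sites(1, score = 0.951, p = 0.03),
             mk_sites(1, score = 0.949, p = 0.03, start = 500),
             mk_sites(1, score = 0.951, p = 0.003, start = 900))
  pool <- build_control_pool(s)
  # 0.951 and 0.949 round to the same affinity bucket
  expect_equal(pool$key[1], pool$key[2])
  # 0.03 vs 0.003: decades -2 vs -3
  expect_false(pool$key[1] == pool$key[3])
  # partition: every site is in exactly one bucket
  set.seed(70)
  s2 <- mk_sites(100, score = runif(100, 0.9, 1),
                 p = 10^runif(100, -4, -1))
  pool2 <- build_control_pool(s2)
  expect_equal(sort(unname(unlist(pool2$index))), 1:100)
})

test_that("matched controls preserve motif, affinity and conservation decade", {
  set.seed(71)
  universe <- rbind(mk_sites(40, motif = "m1", score = 0.95, p = 0.01),
                    mk_sites(30, motif = "m2", score = 0.95, p = 0.01,
                             start = 5000 + seq_len(30) * 100))
  pool <- build_control_pool(universe)
  cobels <- data.frame(chrom = "chr1", start = c(100, 5100),
                       end = c(108, 5108), strand = "+",
                       site_start = c(100, 5100), site_end = c(108, 5108),
                       motif_id = c("m1", "m2"),
                       ancestral_score = 0.95, conservation_p = 0.01,
                       stringsAsFactors = FALSE)
  for (seed in 1:50) {
    ctl <- sample_matched_control_set(cobels, pool, seed)
    expect_equal(nrow(ctl), 2)
    expect_equal(ctl$motif_id, cobels$motif_id)
    expect_equal(round(ctl$score, 2), round(cobels$ancestral_score, 2))
    expect_equal(floor(log10(ctl$conservation_p)),
                 floor(log10(cobels$conservation_p)))
    # own site excluded when alternatives exist
    expect_false(any(ctl$start == cobels$start))
  }
})

test_that("singleton buckets fall back to the site itself", {
  universe <- mk_sites(1, motif = "solo")
  pool <- build_control_pool(universe)
  cobels <- data.frame(chrom = "chr1", start = 100, end = 108,
                       strand = "+", site_start = 100, site_end = 108,
                       motif_id = "solo", ancestral_score = 0.95,
                       conservation_p = 0.01, stringsAsFactors = FALSE)
  ctl <- sample_matched_control_set(cobels, pool, 1)
  expect_equal(ctl$start, 100)
})

test_that("bucket sampling is uniform", {
  universe <- mk_sites(10)
  pool <- build_control_pool(universe)
  cobel <- data.frame(chrom = "chr1", start = 100, end = 108, strand = "+",
                      site_start = 100, site_end = 108, motif_id = "m1",
                      ancestral_score = 0.95, conservation_p = 0.01,
                      stringsAsFactors = FALSE)
  draws <- vapply(1:1000, function(seed)
    sample_matched_control_set(cobel, pool, seed)$start, numeric(1))
  # 9 candidate sites (own site excluded); 3 sigma binomial band
  counts <- table(draws)
  expect_equal(length(counts), 9)
  expected <- 1000 / 9
  sigma <- sqrt(1000 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("empirical top-term p is the plain hit fraction", {
  tops <- c(rep("A", 3), rep("B", 5), rep(NA, 9992))
  r <- empirical_top_term_p("A", tops, "A")
  expect_equal(r$p, 3e-4)
  expect_equal(r$n_hits, 3)
  r2 <- empirical_top_term_p("A", tops, c("A", "B"))
  expect_equal(r2$p, 8e-4)
  # no hits
  expect_equal(empirical_top_term_p("Z", rep(NA_character_, 100),
                                    "Z")$p, 0)
  # target_set = everything counts every passing shuffle
  r3 <- empirical_top_term_p("A", tops, c("A", "B", "C"))
  expect_lte(r3$p, 1)
  expect_equal(r3$n_hits, 8)
})

test_that("p-value products and occurrence rates are plain arithmetic", {
  expect_equal(combine_pvalues_product(0.37), 0.37)
  expect_equal(combine_pvalues_product(c(0.5, 0.5)), 0.25)
  expect_error(combine_pvalues_product(numeric(0)), "no p-values")

  expect_equal(occurrence_rate("A", c("B", "C", NA)), 0)
  expect_equal(occurrence_rate("A", c(rep("A", 5), rep("B", 95))), 0.05)
  expect_error(occurrence_rate("A", character(0)), "empty")
})

test_that("cohort allele frequencies and the rarity filter agree with brute force", {
  cobels <- data.frame(
    chrom = "chr1", start = c(10, 50, 90), end = c(18, 58, 98),
    strand = "+", motif_id = "m", tf = "t",
    variant_ids = c("chr1:12:A>G", "chr1:55:C>T", "chr1:93:G>A"),
    stringsAsFactors = FALSE)
  mkv <- function(pos, alt) data.frame(chrom = rep("chr1", length(pos)),
                                       pos = pos, ref = rep("A", length(pos)),
                                       alt = alt, stringsAsFactors = FALSE)
  cohort <- list(
    mkv(c(12, 55), c("G", "T")),   # carries cobel 1 and 2
    mkv(12, "G"),                  # carries cobel 1
    mkv(55, "C"),                  # different allele: carries none
    mkv(numeric(0), character(0))) # carries none
  f <- cohort_allele_frequency(cobels, cohort)
  expect_equal(f, c(2 / 4, 1 / 4, 0))
  expect_equal(filter_by_frequency(cobels, f, 0.01)$start, 90)
  expect_equal(filter_by_frequency(cobels, f, 0.3)$start, c(50, 90))
  expect_equal(nrow(filter_by_frequency(cobels, f, 0.5)), 3)
})
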