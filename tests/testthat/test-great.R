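test_that("basal-plus-extension domains follow the geometry rules", {
  cfg <- great_config()
  sizes <- c(chrZ = 10000000L)

  # lone plus-strand gene: basal [tss-5000, tss+1000), extension +/- 1 Mb
  g <- data.frame(symbol = "g1", chrom = "chrZ", tss = 5000000,
                  strand = "+", stringsAsFactors = FALSE)
  d <- basal_plus_extension_domains(g, sizes, cfg)
  expect_equal(d$basal_start, 4995000)
  expect_equal(d$basal_end, 5001000)
  expect_equal(d$start, 3995000)
  expect_equal(d$end, 6001000)

  # two plus-strand genes 100 kb apart: extensions stop at the
  # neighbour's basal boundary
  g2 <- data.frame(symbol = c("a", "b"), chrom = "chrZ",
                   tss = c(5000000, 5100000), strand = "+",
                   stringsAsFactors = FALSE)
  d2 <- basal_plus_extension_domains(g2, sizes, cfg)
  expect_equal(d2$end[d2$symbol == "a"], 5095000)   # b's basal start
  expect_equal(d2$start[d2$symbol == "b"], 5001000) # a's basal end

  # clipping at the chromosome start
  g3 <- data.frame(symbol = "edge", chrom = "chrZ", tss = 1000,
                   strand = "+", stringsAsFactors = FALSE)
  d3 <- basal_plus_extension_domains(g3, sizes, cfg)
  expect_equal(d3$basal_start, 0)
  expect_equal(d3$start, 0)

  # minus strand mirrors the geometry
  g4 <- data.frame(symbol = "m", chrom = "chrZ", tss = 5000000,
                   strand = "-", stringsAsFactors = FALSE)
  d4 <- basal_plus_extension_domains(g4, sizes, cfg)
  expect_equal(d4$basal_end - d4$basal_start, 6000)

  expect_error(basal_plus_extension_domains(
    data.frame(symbol = "x", chrom = "chrZ", tss = 2e7, strand = "+"),
    sizes, cfg), "beyond")
})

test_that("term genome fractions use domain unions", {
  ont <- make_toy_ontology("T_target", c("gA", "gB"), c("gC", "gD"),
                           n_terms = 4)
  domains <- data.frame(
    symbol = c("gA", "gB", "gC", "gD"), chrom = "chr1",
    tss = c(1000, 3000, 5000, 7000), strand = "+",
    basal_start = c(900, 2900, 4900, 6900),
    basal_end = c(1100, 3100, 5100, 7100),
    start = c(0, 2000, 4000, 6000), end = c(1000, 3000, 5000, 7000),
    stringsAsFactors = FALSE)
  # two disjoint 1 kb domains on a 100 kb genome
  expect_equal(term_genome_fraction("T_target", ont, domains, 100000), 0.02)
  # a term with no annotated genes covers nothing
  ont0 <- ontology(data.frame(term = c("t", "u"), name = c("t", "u")),
                   data.frame(child = "u", parent = "t"),
                   data.frame(gene = "gA", term = "u"))
  expect_equal(term_genome_fraction("t", ont0, domains[0, ], 1000), 0)
  # overlap counted once
  dov <- domains[1:2, ]
  dov$start <- c(0, 500)
  dov$end <- c(1000, 1500)
  expect_equal(term_genome_fraction("T_target", ont, dov, 10000),
               (1000 + 1000 - 500) / 10000)
})

test_that("binomial region test equals the exhaustive tail", {
  r <- binomial_region_test(10, 7, 0.3)
  expect_equal(r$p_value, oracle_binom_tail(10, 7, 0.3))
  expect_equal(r$expected, 3)
  expect_equal(r$fold, 7 / 3)

  expect_equal(binomial_region_test(50, 0, 0.2)$p_value, 1)
  expect_true(binomial_region_test(10, 3, 0)$degenerate)

  # monotone decreasing in k
  ps <- vapply(0:10, function(k) binomial_region_test(10, k, 0.3)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  # fold * expected = k
  set.seed(60)
  for (i in 1:10) {
    n <- sample(10:5000, 1)
    p <- runif(1, 0.001, 0.5)
    k <- sample.int(n, 1)
    r <- binomial_region_test(n, k, p)
    expect_equal(r$fold * r$expected, k, tolerance = 1e-9)
  }
})

test_that("hypergeometric gene test equals enumeration", {
  expect_equal(hypergeometric_gene_test(10, 5, 4, 4),
               choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(hypergeometric_gene_test(20, 8, 6, 0), 1)
  set.seed(61)
  for (i in 1:10) {
    N <- sample(5:10, 1)
    K <- sample.int(N - 1, 1)
    n_hit <- sample.int(N - 1, 1)
    k_hit <- sample(0:min(K, n_hit), 1)
    expect_equal(hypergeometric_gene_test(N, K, n_hit, k_hit),
                 oracle_hyper_tail(N, K, n_hit, k_hit),
                 tolerance = 1e-12, info = paste(N, K, n_hit, k_hit))
  }
  expect_error(hypergeometric_gene_test(10, 5, 4, 5), "inconsistent")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 1.0)), c(0.04, 0.04, 0.04, 1.0))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(62)
  for (i in 1:10) {
    p <- runif(sample(2:20, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("related term groups walk the DAG with set semantics", {
  terms <- data.frame(term = c("r", "a", "b", "c", "d"),
                      name = c("r", "a", "b", "c", "d"))
  # diamond: d is reachable from a via b and via c
  edges <- data.frame(child = c("a", "b", "c", "d", "d"),
                      parent = c("r", "a", "a", "b", "c"))
  ann <- data.frame(gene = "g1", term = "d")
  ont <- ontology(terms, edges, ann)
  expect_equal(related_term_group(ont, "d"), "d")
  expect_setequal(related_term_group(ont, "a"), c("a", "b", "c", "d"))
  expect_setequal(related_term_group(ont, "r"), c("r", "a", "b", "c", "d"))
  expect_error(related_term_group(ont, "zz"), "unknown")
  # propagation: g1 annotated to d reaches every ancestor
  expect_true(all(vapply(c("r", "a", "b", "c", "d"),
                         function(t) "g1" %in% ont$genes[[t]], logical(1))))
})

test_that("ontology construction rejects cycles", {
  terms <- data.frame(term = c("a", "b"), name = c("a", "b"))
  edges <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(ontology(terms, edges, data.frame(gene = "g", term = "a")),
               "cycle")
})

test_that("enrichment ranks terms and the top selection applies all filters", {
  set.seed(63)
  sizes <- c(chr1 = 100000L)
  genes <- data.frame(symbol = sprintf("g%02d", 1:10), chrom = "chr1",
                      tss = seq(5000, 95000, by = 10000), strand = "+",
                      stringsAsFactors = FALSE)
  ont <- make_toy_ontology("T_target", genes$symbol[1:3],
                           genes$symbol[4:10], n_terms = 5)
  # plant 12 regions in the target genes' basal domains
  regions <- do.call(rbind, lapply(genes$tss[1:3], function(t)
    data.frame(chrom = "chr1", start = t - 4000 + (0:3) * 800,
               end = t - 4000 + (0:3) * 800 + 10)))
  res <- great_enrichment(regions, genes, sizes, ont)
  expect_s3_class(res, "great_results")
  top <- rank_and_select_top(res)
  expect_equal(top$term, "T_target")
  expect_equal(top$n, nrow(regions))
  expect_equal(top$k, 12)
  # fold/expected consistency
  expect_equal(top$expected * top$fold, top$k, tolerance = 1e-9)
  # ancestors cover at least their descendants' genome fraction
  expect_gte(res$p[res$term == "T_parent"], res$p[res$term == "T_target"])
  expect_gte(res$p[res$term == "T_root"], res$p[res$term == "T_parent"])
  # brute-force filter-and-sort agreement
  ok <- res$binom_q <= 0.05 & res$hyper_q <= 0.05 & res$fold >= 2
  cand <- res[ok, ]
  cand <- cand[order(cand$binom_p, -cand$fold, cand$term), ]
  expect_equal(top$term, cand$term[1])
  # no candidate -> NULL
  none <- res
  none$fold <- 1
  expect_null(rank_and_select_top(none))
})
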