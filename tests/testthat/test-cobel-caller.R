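write_test_vcf <- function(lines, path = withr::local_tempfile(
                             fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               lines), path)
  path
}

test_that("VCF loading keeps SNVs, splits multi-allelics, 0-bases positions", {
  path <- write_test_vcf(c(
    "chr1\t101\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",      # SNV het
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t1/1",      # SNV hom
    "chr1\t300\t.\tC\tCTT\t.\tPASS\t.\tGT\t0/1",    # insertion -> dropped
    "chr1\t400\t.\tT\tA,G\t.\tPASS\t.\tGT\t1/2",    # multiallelic SNV
    "chr1\t500\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"))     # SNV het
  v <- load_variants(path)
  expect_equal(nrow(v), 5)  # 3 plain SNVs + 2 alts of the multiallelic
  expect_equal(v$pos[v$id == "chr1:100:A>T"], 100)
  expect_equal(v$zygosity[v$pos == 199], "hom")
  expect_equal(sort(v$alt[v$pos == 399]), c("A", "G"))
  expect_equal(attr(v, "n_skipped"), 1)
  expect_false(any(v$pos == 299))
})

test_that("genotypes gate which alleles are returned", {
  path <- write_test_vcf(c(
    "chr1\t10\t.\tA\tC\t.\tPASS\t.\tGT\t0/0",   # not carried
    "chr1\t20\t.\tA\tC,G\t.\tPASS\t.\tGT\t0/2"  # only second alt carried
  ))
  v <- load_variants(path)
  expect_equal(nrow(v), 1)
  expect_equal(v$alt, "G")
  expect_equal(v$zygosity, "het")
})

test_that("pgSnp rows are polarised against the reference genome", {
  genome <- c(chr1 = "ACGTACGTAC")
  path <- withr::local_tempfile(fileext = ".pgSnp")
  writeLines(c("chr1\t2\t3\tG/T\t2\t10,10\t0,0",   # ref G -> alt T het
               "chr1\t5\t6\tA\t1\t20\t0"), path)   # ref C -> alt A hom
  v <- load_variants(path, format = "pgsnp", genome = genome)
  expect_equal(v$pos, c(2, 5))
  expect_equal(v$ref, c("G", "C"))
  expect_equal(v$alt, c("T", "A"))
  expect_equal(v$zygosity, c("het", "hom"))
})

test_that("ancestral polarisation keeps only derived variants", {
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A",
                  alt = c("G", "G", "G"),
                  zygosity = "het", id = c("a", "b", "c"),
                  stringsAsFactors = FALSE)
  outgroup <- data.frame(chrom = "chr1", pos = c(10, 20),
                         base = c("A", "G"), stringsAsFactors = FALSE)
  kept <- ancestral_filter(v, outgroup)
  # pos 10: outgroup matches ref -> kept; pos 20: reference not ancestral;
  # pos 30: no orthologous base -> cannot polarise
  expect_equal(kept$id, "a")
})

test_that("the caller scores joint substitutions, merges overlaps, and keeps the worst eroder", {
  # genome carrying one strong site for each of three overlapping motifs
  set.seed(50)
  base <- "AAAACGTTTTCCCGGGAAAT"
  genome <- c(chr1 = paste0("TTTTT", base, "TTTTT"))
  mk_pwm <- function(id, s, eps) {
    cons <- strsplit(s, "")[[1]]
    m <- matrix(eps, 4, length(cons),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(cons, rownames(m)), seq_along(cons))] <- 1 - 3 * eps
    pwm(m, id, pseudocount = 0)
  }
  # three sites overlapping position 12 (0-based), different sharpness =>
  # different drops from the same variant
  p1 <- mk_pwm("m1", substr(genome, 9, 16), 0.01)
  p2 <- mk_pwm("m2", substr(genome, 11, 18), 0.05)
  p3 <- mk_pwm("m3", substr(genome, 12, 15), 0.10)
  pwms <- list(m1 = p1, m2 = p2, m3 = p3)
  sites <- data.frame(
    chrom = "chr1", start = c(8, 10, 11), end = c(16, 18, 15),
    strand = "+", motif_id = c("m1", "m2", "m3"),
    tf = c("t1", "t2", "t3"), score = 1, n_species = 6,
    branch_length = 2.5, conservation_p = 0.05, stringsAsFactors = FALSE)
  ref_base <- substr(genome[["chr1"]], 13, 13)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  variants <- data.frame(chrom = "chr1", pos = 12, ref = ref_base,
                         alt = alt_base, zygosity = "het", id = "v1",
                         stringsAsFactors = FALSE)

  # expected drops through the scoring oracle
  drops <- vapply(1:3, function(i) {
    s <- sites[i, ]
    w_ref <- substr(genome[["chr1"]], s$start + 1, s$end)
    w_alt <- w_ref
    substr(w_alt, 12 - s$start + 1, 12 - s$start + 1) <- alt_base
    (oracle_match_score(pwms[[s$motif_id]]$freqs, w_ref) -
       oracle_match_score(pwms[[s$motif_id]]$freqs, w_alt)) /
      oracle_match_score(pwms[[s$motif_id]]$freqs, w_ref)
  }, numeric(1))
  expect_true(all(drops >= 0.05))  # all three candidates erode

  cob <- call_cobels(sites, variants, pwms, genome)
  expect_equal(nrow(cob), 1)                      # merged into one locus
  expect_equal(cob$start, 8)
  expect_equal(cob$end, 18)
  expect_equal(cob$motif_id, sites$motif_id[which.max(drops)])
  expect_equal(cob$drop, max(drops), tolerance = 1e-9)
  expect_equal(cob$n_sites, 3)

  # a variant that overlaps no site contributes nothing
  far <- data.frame(chrom = "chr1", pos = 28, ref = "T", alt = "A",
                    zygosity = "het", id = "v2", stringsAsFactors = FALSE)
  expect_equal(nrow(call_cobels(sites, far, pwms, genome)), 0)

  # raising the threshold never adds loci
  n_by_drop <- vapply(c(0, 0.05, 0.2, 0.5), function(d)
    nrow(call_cobels(sites, variants, pwms, genome,
                     call_config(min_drop = d))), integer(1))
  expect_true(all(diff(n_by_drop) <= 0))

  # no variants -> no loci
  expect_equal(nrow(call_cobels(sites, variants[0, ], pwms, genome)), 0)
})

test_that("affinity-gaining alleles are never called", {
  m <- matrix(0.05, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(c(1, 2, 3, 4), 1:4)] <- 0.85
  p <- pwm(m, "gain", pseudocount = 0)  # consensus ACGT
  genome <- c(chr1 = "TTTTTACTTTTTTT")  # near-site AC TT at 5..9
  sites <- data.frame(chrom = "chr1", start = 5, end = 9, strand = "+",
                      motif_id = "gain", tf = "g", score = 0.5,
                      n_species = 6, branch_length = 2.5,
                      conservation_p = 0.05, stringsAsFactors = FALSE)
  # T -> G at offset 2 moves the window toward consensus (gain)
  v <- data.frame(chrom = "chr1", pos = 7, ref = "T", alt = "G",
                  zygosity = "het", id = "v", stringsAsFactors = FALSE)
  expect_equal(nrow(call_cobels(sites, v, list(gain = p), genome)), 0)
})

empty_cobels_for_test <- function() {
  data.frame(chrom = character(), tf = character(),
             zygosity = character(), stringsAsFactors = FALSE)
}

test_that("summaries add up", {
  s <- summarize_cobels(empty_cobels_for_test())
  expect_equal(s$total, 0)
  cob <- data.frame(chrom = "chr1", start = c(1, 10, 20),
                    end = c(9, 18, 28), strand = "+",
                    motif_id = c("a", "a", "b"), tf = c("TFa", "TFa", "TFb"),
                    zygosity = c("het", "hom", "het"),
                    stringsAsFactors = FALSE)
  s <- summarize_cobels(cob)
  expect_equal(s$total, 3)
  expect_equal(s$het, 2)
  expect_equal(s$hom, 1)
  expect_equal(sum(s$per_tf$n), 3)
})

test_that("planted erosions are recovered end to end", {
  scr <- get_small_screen()
  man <- get_fixture("small42", small_fixture_config())
  truth <- man$truth
  eroded <- truth[truth$eroded, ]
  # every eroded planted site that survived conservation filtering is called
  site_key <- paste(scr$sites$chrom, scr$sites$start)
  surviving <- eroded[paste(eroded$chrom, eroded$start) %in% site_key, ]
  hit <- vapply(seq_len(nrow(surviving)), function(i)
    any(scr$cobels$chrom == surviving$chrom[i] &
          scr$cobels$start <= surviving$start[i] &
          scr$cobels$end >= surviving$end[i]), logical(1))
  expect_true(all(hit))
  expect_gte(nrow(surviving) / nrow(eroded), 0.8)
  # no locus without a variant: every called locus contains >= 1 variant
  vars <- scr$variants
  in_locus <- vapply(seq_len(nrow(scr$cobels)), function(i)
    any(vars$chrom == scr$cobels$chrom[i] &
          vars$pos >= scr$cobels$start[i] &
          vars$pos < scr$cobels$end[i]), logical(1))
  expect_true(all(in_locus))
})
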