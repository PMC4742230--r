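# cobelr

Screening personal genomes for **erosion of conserved transcription
factor binding sites** — and asking which gene function or phenotype the
eroded sites congregate next to.

Most personal variants fall in the non-coding genome, where their effect
is hard to interpret one variant at a time. `cobelr` takes the aggregate
view: it collects every place where an individual's *derived* variant
weakens a binding site that has been conserved across mammals — a
**conserved binding site eroding locus (CoBEL)** — and then tests whether
those loci pile up in the regulatory domains of genes sharing a function
or phenotype. The package is aimed at regulatory-genomics researchers who
want to run, probe, or extend such a screen at small scale, with every
stage exposed as an ordinary R function.

## The method

1. **Binding sites.** Each motif is a position frequency matrix
   `f(i, b)`. A window `b_1..b_L` is scored with the MATCH scheme: the
   information vector `I(i) = Σ_b f(i,b) ln(4 f(i,b))` weights each
   position, the raw score `Σ_i I(i) f(i, b_i)` is min–max normalised to
   `[0, 1]`, and both strands of the reference genome are scanned.
2. **Conservation.** A site is kept only if ≥ 5 aligned species preserve
   it (their orthologous, gap-free window also scores above the cutoff),
   the preserving species span ≥ 2 substitutions/site of neutral branch
   length, and a conservation p-value ≤ 0.05, estimated by scanning
   CpG-preserving shuffles of the motif in the same alignment block. Per
   motif, at most the top 5,000 sites are retained.
3. **Erosion.** Variants are polarised against an outgroup (the
   reference allele must match the outgroup base, the individual's
   allele must differ — i.e. be derived), substituted jointly into each
   overlapping site, and the site is rescored. A relative MATCH-score
   drop ≥ 5% is an erosion; overlapping erosions merge into one locus.
4. **Enrichment.** Loci are tested GREAT-style against an ontology DAG:
   each gene gets a basal (5 kb up / 1 kb down of the TSS) plus
   extension (≤ 1 Mb, bounded by neighbouring basal domains) regulatory
   domain; for each term the binomial tail
   `P(X ≥ k), X ~ Bin(n, p)` — with `p` the genome fraction covered by
   the annotated genes' domain union — is combined with a hypergeometric
   gene-level test, both at FDR ≤ 0.05 and binomial fold ≥ 2.
5. **Significance.** Matched-control permutations (each locus replaced
   by a random conserved site of the same motif, identical affinity and
   same conservation-p order of magnitude), cohort occurrence rates, and
   a constrained medical-history shuffling test.

## A worked example

The package ships a synthetic-data generator that writes every input the
screen consumes — reference FASTA, MAF alignment, newick tree, motif
library, gene models, ontology, a VCF and an outgroup track — with
planted, perfectly conserved sites near the genes of one ontology term,
80% of which carry an eroding variant:

```r
library(cobelr)

cfg <- fixture_config(n_species = 6, genome_length = 100000, n_genes = 12,
                      n_terms = 6, n_target_genes = 4,
                      n_planted_sites_per_target_gene = 4,
                      n_decoy_sites_per_gene = 2, n_motifs = 3,
                      background_snv_rate = 5e-5, seed = 42)
man <- simulate_screen_inputs(cfg, "fixture")
rc  <- run_config_from_manifest(man, seed = 42, n_control_shuffles = 200,
                                output_dir = "run")
res <- run_screen(rc, do_nulls = TRUE, null_ancestor = "T_parent")
res
#> CoBEL screen
#>   conserved sites: 36
#>   CoBEL loci:      13
#>   top term:        T_target (planted target term), k=13, fold=2.03, binom_q=0.000616
#>   null exact-term empirical p: 0 (200 shuffles)
head(res$enrichment)
#>       term                  name  k expected  fold   binom_p   binom_q hyper_q
#> 1 T_target   planted target term 13    6.414 2.027 0.0001026 0.0006156 0.01212
#> 2 T_parent parent of target term 13    8.472 1.534 0.0038234 0.0114701 0.09091
#> 3   T_root              toy root 13   13.000 1.000 1.0000000 1.0000000 1.00000
#> 4  T_dec01          decoy term 1  0    4.702 0.000 1.0000000 1.0000000 1.00000
#> ...
```

Reading the output: 36 planted sites survived the conservation filters,
13 of them were eroded by the individual's derived variants, and the 13
loci concentrate in the regulatory domains of the four `T_target` genes
— 13 observed against 6.4 expected from the 49% genome coverage of
those domains, fold 2.03, binomial FDR 6 × 10⁻⁴, so the planted term is
the top (and only) passing enrichment. The matched-control p of 0 over
200 shuffles says random same-affinity, same-conservation sites for the
same motifs almost never reproduce that top term.

Outputs land in `run/`: `conserved_sites.bed`, `cobels.bed` (BED6+ with
ancestral/derived scores and the affinity drop), `enrichment.tsv`,
`top_term.json` and `screen.log`, each stamped with the package version,
a configuration hash and the seed; identically configured runs are
byte-identical.

A thin CLI over the same functions is installed at
`system.file("scripts", "cobel_screen.R", package = "cobelr")` with
`simulate`, `screen` and `cohort` subcommands.

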