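---
title: "The CoBEL screen: model, parameters and design choices"
author: "cobelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CoBEL screen: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobelr)
```

## The model

A conserved binding site eroding locus (CoBEL) is defined by three
nested conditions on a genomic window: (i) it matches a transcription
factor's binding preference in the reference genome, (ii) the match has
been preserved across a panel of related species for long enough that
its loss plausibly carries a fitness cost, and (iii) one individual's
derived allele measurably weakens the match. The screen's claim is
statistical, not mechanistic: individually these loci are weak evidence,
but if an individual's set of CoBELs concentrates next to genes sharing
one function or phenotype far beyond chance, the aggregate points at a
dysregulated process.

### Binding affinity

Binding preferences are position frequency matrices $f(i,b)$,
$b \in \{A,C,G,T\}$, $i = 1..L$. A window $b_1..b_L$ is scored with the
MATCH scheme. Each position is weighted by its information content

$$I(i) = \sum_b f(i,b)\,\ln\!\big(4 f(i,b)\big),$$

which is 0 for an uninformative (uniform) column and $\ln 4$ for a
deterministic one; zero-frequency terms contribute 0. The raw score
$\sum_i I(i) f(i, b_i)$ is min–max normalised by the smallest and
largest raw scores attainable at each position, so every score lies in
$[0,1]$, the consensus scores exactly 1 and the per-position-minimal
window exactly 0. Uninformative columns thus contribute nothing to the
normalised score, and a mismatch at a sharp position costs much more
than one at a degenerate position.

A pseudocount (default $10^{-3}$, configurable, 0 allowed) is added to
all frequencies and columns renormalised when a matrix is constructed,
keeping the logarithms finite for matrices with hard zeros. Windows
containing non-A/C/G/T characters are skipped rather than scored. Dimer
motifs are scored as ordinary concatenated matrices — the library
supplies them pre-concatenated — and both strands are scanned, the
reverse strand via the reverse-complemented matrix.

### Erosion

For a site overlapped by an individual's variants, all alternate alleles
inside the window are substituted jointly — the individual's derived
haplotype — and the window rescored. The erosion statistic is the
*relative* drop $(s_\mathrm{ref} - s_\mathrm{alt})/s_\mathrm{ref}$, and
a site is called eroded when the drop is at least `min_drop` (default
0.05). The wording "lowers binding affinity by five per cent" admits a
relative or an absolute reading; we adopt the relative one because it
treats strong and weak ancestral sites symmetrically, and expose the
absolute difference behind `call_config(relative_drop = FALSE)` for
sensitivity analyses. A site whose reference window scores 0 cannot be
polarised and is flagged unscoreable. Overlapping eroded sites merge
into one locus represented by the site with the greatest drop (ties:
higher ancestral score, then leftmost); heterozygous and homozygous
erosions count equally (zygosity is recorded but unused downstream).

Variants enter the screen only after ancestral polarisation: the
reference allele must equal the outgroup's orthologous base (so the
reference is most likely ancestral) and the individual's allele must
differ from it. Positions the outgroup does not cover cannot be
polarised and are dropped.

### Conservation

A non-reference species *preserves* a site when its aligned orthologous
window is gap-free and scores at least the same cutoff used for the
reference scan — one threshold rather than two, since nothing in the
data motivates a second free parameter; a base-identity criterion would
be stricter and is deliberately not used, because compensated
substitutions that preserve the match are common in real alignments.
Conservation depth is the total branch length (substitutions/site) of
the subtree induced by the preserving species plus the reference.
Defaults: at least 5 preserving species and at least 2
substitutions/site.

Species count and branch length do not control for *regional*
conservation — a site inside a generally frozen region is trivially
preserved. The conservation p-value therefore compares the site against
CpG-preserving shuffles of its own motif scanned **within the same
alignment block**: locality is the operational stand-in for "similarly
conserved regions", controlling for regional conservation without
needing a genome-wide conservation map. The shuffle keeps any adjacent
column pair whose consensus reads CpG glued in order, preserving the
motif's CpG content (and hence its exposure to deamination-driven
turnover) while destroying its phase. With $N$ shuffles and $c$ of them
achieving a preserving branch length at least the site's, the p-value is
$(c+1)/(N+1)$ — never exactly 0, and 1 whenever the site is preserved
nowhere. The default $N = 19$ is the smallest count whose minimum
p-value $1/20$ still clears the 0.05 filter; raising `n_shuffles_for_p`
sharpens the estimate linearly in cost. Per motif, at most
`max_sites_per_motif` (default 5,000) sites are kept, ranked by
conservation p, then match score, then coordinate — the ranking key is a
design choice; conservation evidence is put first because the
p-value is the filter the cap interacts with. Sites spanning MAF block
boundaries are dropped rather than stitched.

### Enrichment

Each gene's regulatory domain is basal-plus-extension: a strand-aware
basal interval of 5,000 bases upstream and 1,000 downstream of the TSS,
extended on each side to the nearest flanking basal-domain boundary of
the adjacent gene or by at most 1 Mb, whichever is closer, clipped at
chromosome ends. Basal domains of different genes may overlap. For every
ontology term (after propagating gene annotations to all ancestors along
`is_a` edges) the union of its genes' extended domains covers a genome
fraction $p$, and the binomial tail $P(X \ge k)$, $X \sim
\mathrm{Bin}(n, p)$, measures region-level surprise; the companion
hypergeometric test asks whether genes with at least one locus are
enriched for the annotation at the gene level, guarding against a single
domain swallowing many loci. A region is attributed to every gene whose
extended domain contains its midpoint — midpoint attribution keeps $k$
well defined where domains overlap; any-overlap attribution is available
via `great_config(attribution = "any_overlap")`. Both tests are
BH-corrected within each ontology namespace, and a top term must pass
binomial FDR ≤ 0.05, hypergeometric FDR ≤ 0.05 and fold ≥ 2; among the
survivors the smallest binomial p wins, ties broken by larger fold and
then term id. Terms with no annotated genes are skipped and do not count
toward the correction. Genome size defaults to the sum of the supplied
chromosome lengths.

### Permutation nulls

The enrichment rejects uniform placement of loci, but eroded or not, the
conserved-site background itself may be biased toward some terms'
domains. The matched-control null replaces each locus with a random
conserved site of the *same motif*, *identical affinity* (equal after
rounding to 2 decimals) and a conservation p of the *same order of
magnitude* (equal `floor(log10 p)`), then reruns the enrichment; the
empirical p is the plain fraction of control sets whose top term matches
(the published scale of such p-values at 10,000 shuffles implies a
count-over-N estimator rather than $(c+1)/(N+1)$, and we follow that
here — unlike the conservation p, a zero is meaningful and reported as
such). A control set whose enrichment passes no filter counts in the
denominator but never as a hit. The locus's own site is excluded
whenever its bucket offers alternatives; an empty bucket falls back to
the same-motif nearest-score site and logs the event. Shuffle $k$ uses
seed $\text{master}+k$, making every stream reproducible and
independently re-runnable.

The medical-history test shuffles person–history assignments under three
constraints — per-person entry counts preserved exactly, the global
entry multiset preserved, and at least 80% of (person, entry) pairings
changed — and counts how often shuffled individuals remain fully
associated with the observed top terms under a fixed gold association
matrix. "Similar number of entries" is enforced as *exactly* preserved
counts, the strictest testable reading. Association by default requires
*every* person's top term to link to at least one of their entries
(again the strictest reading of associating "a set" of individuals);
`min_matches` relaxes it to at-least-$k$-of-$n$. Because entries within
a person are unordered, "pairings changed" is computed as the complement
of the per-person multiset overlap with the original histories.

## The synthetic study conditions

`simulate_screen_inputs()` writes every input the pipeline consumes.
Its defaults are the package's reference study conditions: 8 aligned
species on a random bifurcating tree with branch lengths uniform on
0.05–0.5 substitutions/site (rescaled up if the total falls below 2, so
a fully preserved site always clears the branch-length filter); a
500 kb uniform-random reference chromosome; 60 genes on alternating
strands; a 12-term, two-level ontology whose target term annotates 8
genes (its parent gets two extra direct annotations, keeping the parent
strictly broader so ties resolve to the planted term); a library of 6
sharp 8-bp motifs (consensus probability 0.91); 5 planted consensus
sites of the target motif per target gene and 2 per other gene — the
latter populate the matched-control pool away from the target genes —
plus scattered decoy-motif sites; erosion of 80% of the target-gene
sites by a variant at the motif's maximum-information position changing
the consensus base to the least-frequent base (a guaranteed 12.5% drop
for an 8-position sharp motif); and background SNVs at $10^{-4}$ per
base. Planted sites sit within ±3 kb of their gene's TSS so exactly one
basal domain covers them, are confined to single MAF blocks, and their
alignment columns are copied unchanged to every species: deterministic
perfect conservation makes filter recovery sharp, at the cost of not
exercising partially conserved sites. Background columns evolve down
the tree by independent base flips with probability
`min(0.75, branch length × substitution_rate_scale)` per branch.

What the generator does *not* emulate — alignment gaps and errors,
realistic substitution and indel processes, CpG hypermutability,
linkage, population structure, motif families with overlapping
preferences, and genome-scale term systems — bounds what passing tests
show: they validate the machinery and its statistics on sharp planted
truth, not performance on real genomes.

For fast unit tests the suite shrinks these conditions (100 kb, 12
genes, 6 species, 6 terms); the headline parameter-recovery checks run
the full defaults over 20 seeds each for signal (top term equals the
planted term, FDR ≤ 0.05, fold ≥ 2, expected in ≥ 95% of seeds) and null
(no passing term, ≥ 90%), and the acceptance script runs one signal and
one null screen plus a 200-set matched-control null.

## Numerical choices and degenerate inputs

* A matrix whose columns are all uniform has zero information; every
  window is simultaneously consensus and anti-consensus and is scored 1.
* Empirical p-values: $(c+1)/(N+1)$ for conservation (a filter —
  zeros must be impossible), $c/N$ for the permutation nulls (a report —
  zeros are informative).
* Affinity buckets round to 2 decimals; conservation decades use
  `floor(log10 p)`; both are the coarsest grids consistent with
  "identical affinity" and "same order of magnitude".
* History shuffling resamples up to 1,000 permutations before declaring
  the constraints unsatisfiable (e.g. a single person).
* All seeded helpers restore the caller's RNG state; derived seeds are
  `master + offset`, kept below $2^{31}$.
* Filtering is idempotent, and ranking ties break deterministically
  (score, then coordinate, then term id), so identically configured
  runs are byte-identical.

## Known limitations

The screen inherits the limits of its inputs: motif libraries are
incomplete and partially redundant; conservation-filtered prediction
misses young, species-specific sites by construction; single-nucleotide
erosions ignore indels, structural variants and phased haplotypes
(multi-sample VCFs use the first sample only); and the enrichment's
binomial assumes loci land independently, which clustered variants
violate. The matched-control null conditions on the observed motif
composition — it cannot detect bias shared by all sites of a motif. At
toy scale the ontology has a dozen terms; multiple-testing behaviour at
the scale of real term systems (~16,000 terms) is not exercised here.
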