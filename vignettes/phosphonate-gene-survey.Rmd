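---
title: "Surveying phosphonate-cycling genes in marine metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying phosphonate-cycling genes in marine metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscycle)
```

## The problem

Phosphonates — organophosphorus compounds with a direct C–P bond — are a
major fraction of the marine dissolved organic phosphorus pool, and their
biosynthesis (marked by *pepM*) and catabolism (substrate-specific 2-AEP
hydrolases such as *phnX* and *phnZ*, and the broad-specificity C-P lyase
marked by *phnI/phnJ/phnM*) shape oceanic phosphorus and methane cycling.
Estimating what fraction of a microbial community carries each of these
genes from short-read metagenomes requires three things this package
provides:

1. **Trustworthy reference databases.** Homology searches against loosely
   annotated protein families produce false positives, so candidate
   sequences are verified by the presence of conserved catalytic,
   substrate-binding, or cofactor-binding residues, and for families that
   resemble common superfamilies (phpC, phnY) additionally by genomic
   neighbourhood: a candidate is only accepted when another
   phosphonate-cycling gene lies nearby on the same contig.
2. **Bias-corrected counting.** Raw hit counts are biased toward longer
   genes (more positions for a read to land on) and toward families where
   genomes carry multiple copies. Both biases are corrected with per-family
   factors computed from the reference databases themselves.
3. **A community-size denominator.** Absolute hit counts depend on
   sequencing depth; dividing by the average abundance of five conserved
   single-copy genes (*recA*, *atpD*, *tufA*, *gyrB*, *hsp70*) converts a
   gene count into the *fraction of community members* carrying the gene.

## The abundance model

For gene $g$ with raw filtered hit count $c_g$ in one sample,

$$\tilde c_g = c_g \cdot \underbrace{\frac{\#\,\mathrm{genomes}_g}{\#\,\mathrm{sequences}_g}}_{\text{copy-number factor}} \cdot \underbrace{\frac{\bar L_{\mathrm{study}}}{\bar L_g}}_{\text{length factor}},$$

where both factors come from the dereplicated (non-redundant) reference
database of $g$, and $\bar L_{\mathrm{study}}$ is the mean sequence length
over all phosphonate databases pooled. The community size proxy is

$$N = \frac{1}{5}\sum_{m \in \mathrm{markers}} c_m \cdot \frac{L_{recA}}{L_m},$$

the mean of the five single-copy marker counts, each scaled to its recA
length equivalent (recA is the shortest marker, so scaling avoids
over-counting from longer markers). Relative abundance is
$100 \cdot \tilde c_g / N$, in percent of community members.

Two scale conventions interact here and are worth being explicit about:
the numerator is normalized to the *study mean* length while the
denominator is normalized to the *recA* length. The estimator therefore
carries an overall factor $\bar L_{\mathrm{study}} / L_{recA}$ relative to
the true carrier fraction. When all reference lengths are equal this
factor is 1 and the estimator is unbiased for the carrier fraction; the
synthetic generator uses that condition as its default (see below). We
compute $\bar L_{\mathrm{study}}$ over the phosphonate databases only, not
the markers — the markers have their own recA-based normalization and
mixing the two would couple the numerator scale to the marker set chosen.

## Screening thresholds

Translated-search hits (12-column tabular format) are reduced to the best
hit per query (max bitscore, ties by min e-value, then input order) and
filtered by per-family minimum percent identity — 50% for *pepM*, *aepY*,
*phnA*, *phnW*, *phnX*, *phnZ*, *phnI*; 55% for *phnM*; 60% for *phpC*,
*mpnS*, *hepD*, *palA*, *phnJ*; 65% for *phnY* — over a minimum alignment
length of 32 aa for 100 bp reads or 40 aa for 125 bp reads. All thresholds
are inclusive (`>=`): a "minimum of 32" admits 32. Alignment length is
taken from column 4 of the tabular format, the only coverage measure the
format carries. Every unique query with a passing hit counts once;
forward and reverse mates carry distinct query ids and both count, and a
read may count toward several families because each family is screened
against its own database. Marker genes pass through the same best-hit and
length filters with a default 50% identity threshold; the threshold is
configurable since single-copy housekeeping genes are well-conserved and
the choice is not critical at these settings.

```{r}
cfg <- screen_config(read_length_bp = 100)
cfg$min_identity_pct[c("pepM", "phnM", "phnJ", "phnY")]
cfg$min_aln_length_aa
```

## Database curation choices

**Residue rules are data, not code.** Rules are supplied as a TSV keyed to
a named anchor sequence per family: `gene, ref_seq_id, ref_position`
(1-based on the *ungapped* anchor), `allowed`, `role`. The package maps
anchor positions through the alignment (`map_reference_positions()`) and
keeps a sequence only if it passes *every* rule. A gap at a rule column is
a failure — absence of the conserved residue is exactly what the rule
tests. Anchor sequences always pass their own rules. An empty rule set is
refused rather than silently keeping everything, unless an explicit
pass-through flag is set.

**Dereplication** mirrors the deterministic behaviour of greedy clustering
tools: sequences are processed longest-first (ties broken
lexicographically by id); each sequence joins the first existing cluster
whose representative it matches at `>= threshold` identity, else it founds
a new cluster. Identity is identical aligned residues over the length of
the shorter sequence under global alignment. The non-redundant database
keeps every cluster member's genome id, so copy-number factors are
computed over the full membership, not just representatives. Sequence
lengths entering the factors are the lengths found in the input FASTA; the
package does not trim.

**Synteny verification** defaults to a window of 10 locus ranks on the
same contig, configurable; "close proximity" has no canonical value and 10
ranks comfortably covers operon-scale neighbourhoods without reaching
across unrelated loci.

**The marine flag** is taken verbatim from metadata — no habitat inference
is attempted, since habitat metadata is typically available for only a
fraction of public genomes.

## The statistics layer

* **Co-occurrence**: for source gene $s$ and co-gene $c$, the fraction of
  genomes carrying $s$ that also carry $c$, computed on the *redundant*
  databases (each genome's own sequences, before clustering). The matrix
  is asymmetric by construction.
* **Diversity**: Shannon $H = -\sum p_i \ln p_i$ over taxonomic-class
  frequencies and Pielou evenness $J = H/\ln S$. Natural log throughout
  (the base is configurable; published evenness values computed with other
  conventions may differ, so we document the formula rather than chase
  any particular printed value).
* **ANOVA / Tukey HSD**: standard one-way decomposition; Tukey
  $q = |\bar x_i - \bar x_j| / \sqrt{\tfrac{MS_W}{2}(\tfrac1{n_i}+\tfrac1{n_j})}$
  with adjusted p from the studentized-range distribution
  (`stats::ptukey`, numerically integrated). With $k=2$ balanced groups
  this reduces exactly to the pooled t-test ($q = \sqrt2\,|t|$), which the
  tests exploit as a closed-form oracle.
* **Phosphate regression**: OLS of $\ln(\text{abundance})$ on
  $\ln(P_i + 0.01)$. The 0.01 µmol/L pseudocount admits samples below the
  phosphate detection limit; it applies to phosphate only. Zero abundances
  are excluded with a reported count rather than pseudocounted, and
  samples with missing phosphate are excluded and counted.
* **Bray-Curtis**: $d(x,y) = \sum|x_i-y_i| / \sum(x_i+y_i)$; all-zero
  samples are an error naming the sample. The matrix is exported as square
  TSV for external ordination — NMDS itself is out of scope since stress
  minimization is standard tooling.
* **ANOSIM**: ranks all pairwise distances (mid-ranks for ties) and forms
  $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$, so $R \in [-1,1]$
  and $R = 1$ under perfect separation. Significance uses the add-one
  permutation estimator $p = (1 + \#\{R^* \ge R\})/(1 + n_{perm})$ with a
  mandatory seed, or exact enumeration of all distinct label arrangements
  for small $n$.

## The synthetic generator

Synthetic data make every stage testable against known ground truth. The
generator emulates the three real inputs: reference databases (families
mutated from a random ancestor, with planted conserved residues, planted
rule violators, planted copy numbers, and locus tables with planted
synteny orphans), communities (Dirichlet-weighted classes, per-gene
carrier probabilities resembling marine survey prevalences, optional
conditional co-occurrence overrides, log-normal abundances), and hit
tables (per-genome counts Poisson with rate
$\propto \text{abundance} \times \text{copies} \times \text{length}$,
identities uniform at-or-above threshold for true hits and strictly below
threshold for decoys, distinct `/1` and `/2` mates).

Three modelling choices matter:

* **The Poisson length-proportional hit model** is the minimal model under
  which the copy-number and length corrections are exactly the right
  inverse transforms. It is the model being *tested*, not a claim about
  real sequencers: real data add GC bias, read-quality structure,
  cross-family homology and alignment noise that the generator does not
  emulate, so passing recovery tests demonstrates correctness of the
  normalization arithmetic, not robustness to those artefacts.
* **Equal reference lengths by default** (350 aa for all families and
  markers). This is the identifiability condition under which the planted
  carrier fraction is the analytic expectation of relative abundance (the
  $\bar L_{\mathrm{study}}/L_{recA}$ factor is 1); it is chosen once as
  the generator's study condition. Length bias itself is exercised by
  dedicated unequal-length checks (a 3× longer gene draws ≈3× the raw
  hits and equal normalized abundance).
* **Decoys strictly below threshold** make filter correctness testable
  exactly: filtered counts must equal planted true-hit counts with zero
  tolerance.

One global seed drives a hierarchical seed tree (hashed per stage, sample
and gene), so identical seeds give byte-identical hit files and any subset
of the outputs reruns reproducibly.

```{r, eval = FALSE}
cfg <- sim_config(seed = 1, n_genomes = 400, n_samples = 1,
                  total_reads = 1e6)
comm <- simulate_community(cfg)
sim <- simulate_hit_tables(comm, "sim/")
counts <- screen_samples(sim$manifest)
```

## Problem sizes and numerical choices

The test and verification suites use sizes chosen to make Monte-Carlo
bounds tight while staying interactive: end-to-end recovery uses 20
communities of 400 genomes at $10^6$ reads (marker counts ≈ 3500, so a
20% gene yields ≈ 700 hits and the per-seed Poisson error is under 4%);
null calibration uses 500 ANOSIM simulations at 199 permutations (the
add-one estimator is exactly calibrated at $\alpha$ a multiple of
$1/200$); regression recovery uses 100 replicates at $n = 50$.
Dereplication is cross-checked against a brute-force all-pairs oracle at
30 sequences, and exact ANOSIM enumeration is limited to $n \le 10$
samples. Recovery assertions use three Monte-Carlo standard errors; exact
assertions (filters, oracles, determinism) use zero tolerance.

Degenerate inputs are errors, not silent results: empty databases when
computing factors, zero total variance in ANOVA, all-zero rows in
Bray-Curtis, single-member groups in ANOSIM, fewer than three usable
points in the regression, and samples with zero community size (excluded
and listed, never imputed).

## Known limitations

* The curation stage consumes alignments; it does not build or trim them
  (use an external aligner), and it does not fetch sequences from genome
  portals.
* The screening stage consumes tabular search output; running the
  translated search itself is out of scope.
* Relative abundances above 100% are possible (a family can out-count the
  marker average, e.g. under multi-copy under-correction) and are flagged
  rather than truncated.
* Published database-derived statistics can only be re-computed when the
  corresponding curated genome–gene table is supplied by the user; the
  package ships no third-party data.
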