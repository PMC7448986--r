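---
title: "Models and methods behind chemrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chemrec` annotates insect chemosensory receptor families (ORs, GRs, IRs)
in genome assemblies by protein-to-genome homology and then tests 1:1
orthologue pairs between sister species for positive selection. This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the protocol leaves room.

## Translated search

Queries are reference receptor proteins; subjects are the six reading
frames of each scaffold. Alignment is local Smith–Waterman with affine
gaps (open −11, extend −1, a gap of length L costing `open + L·extend`)
over BLOSUM62. Two deliberate choices:

* **Stop codons score −4** — the mismatch floor — instead of terminating
  the alignment. Pseudogene exons must still seed hits, because the
  protocol annotates pseudogenes rather than discarding them.
* **E-values use fixed ungapped Karlin–Altschul constants**
  (λ = 0.3176, K = 0.134 for BLOSUM62), with `E = K·m·n·e^(−λS)`, `m` the
  query length and `n` the total translated search space. Absolute
  e-values therefore differ from NCBI tBLASTn, which estimates gapped
  parameters per search; the *semantics* of the `1e-5` cutoff — a score
  floor that scales with the search space — are preserved, and that is
  what the downstream contract needs.

On scaffold-scale frames the search seeds on exact amino-acid 4-mers,
confirmed BLAST-style by a second hit on the same diagonal within 40
residues, and runs full dynamic programming inside windows around
confirmed seed clusters; additional hits per window are extracted by
masking and realigning. Reported scores are always true DP scores of the
reported region, and small inputs skip seeding entirely, which is why the
search agrees exactly with an exhaustive Smith–Waterman oracle on the
random instances the test suite draws.

## Chaining and loci

Hits are chained "exon by exon": two HSPs join when they share scaffold
and strand, their genomic gap is at most `max_intron` (default 15 kb),
the chain span stays under `max_locus_span` (50 kb), and their query
intervals are colinear with the genomic order with at most 10 aa overlap.
A backward jump in query coverage — the signature of the next member of a
tandem array — forces a chain split. Chains from different queries with
overlapping genomic extents merge into one locus, so every HSP belongs to
exactly one locus; loci gain 2-kb flanks, clipped at scaffold ends.

The chaining limits are pipeline parameters, not biological claims: 15 kb
comfortably exceeds observed beetle receptor introns while keeping
neighbouring genes separable. Because a weak cross-paralog chain can
still fuse two adjacent genes into one locus, the model-building step
performs *locus fission*: after the best gene model claims its span, HSPs
lying entirely outside it are re-queued as their own loci (at most two
fission rounds), and overlapping duplicate models arising from the
re-attached flanks are collapsed onto the best-scoring one. Without
fission, roughly one gene in ten is silently lost to fusion on the
benchmark genome; with it, recovery is complete.

## Spliced gene models

For each locus the references with the highest summed HSP bit scores
(`top_n_references = 5`; references far below the leader are skipped) are
aligned to the locus DNA by a dynamic program whose states mirror what a
receptor gene can contain:

* codon match (BLOSUM62 on the translated codon),
* codon insertion/deletion (affine, 3-bp steps),
* single-base frameshift (2-bp or 4-bp step, −20, emitted as `X` and
  counted),
* intron: a zero-emission jump from a `GT` donor to an `AG` acceptor of
  at least 30 bp, flat penalty −10, allowed only between codons,
* stop codon (−15, translated `X`, counted).

The penalties are chosen so that one frameshift outweighs any single
mismatch but never rejects a model, since frameshifts are exactly what
pseudogene calling needs to see. Only canonical GT–AG introns are
modelled; GC–AG donors (a few percent of real introns) are a documented
blind spot. The full DP is run for every locus — at the locus sizes the
chainer can emit (≤ 50 kb plus flanks) memory and time are unproblematic,
so no banded approximation is used. Ties between candidate models break
by fewer frameshifts, fewer stops, longer protein, then lexicographic
reference id, making model choice fully deterministic.

## Retention, pseudogenes, two rounds

A model with any internal stop or frameshift is a pseudogene and is kept
regardless of length — pseudogene fragments are part of the family's
history and are counted separately. Clean models are `full` at
≥ 0.9 × reference length (the protocol distinguishes full-length counts
without defining the cutoff; 0.9 is the package's declared choice,
config-exposed), `partial` at ≥ half the reference length *and* strictly
more than 190 aa, and rejected otherwise. Length filters are always
evaluated against the external (cross-species) reference, not against
round-1 proteins, which would otherwise certify their own length.

Identification runs twice: round 2 adds the retained round-1 proteins to
the query set, merges loci with stable round-1 identifiers, rebuilds and
re-classifies all models. The gain is real: a family member whose exons
are individually too diverged from the external references to clear the
e-value floor is found once a close paralog from round 1 joins the query
set. Finally, candidates whose best database hit is a decoy, or whose
best family beats the runner-up by fewer than 5 bits, are removed as
family-inconsistent.

## Completeness accounting

Assembled transcripts stand in for the de novo transcriptome: a
transcript is a family candidate iff its best translated alignment to a
family reference spans at least 120 aa (OR, GR) or 190 aa (IR), and it
counts as found in the annotation iff it aligns to an annotated family
protein at ≥ 90% identity over at least that span (the identity threshold
is the package's declared choice). The remainder are missing — expressed
family members absent from the assembly or the annotation.

## Trees and orthologue pairs

Family proteins (ORs < 230 aa and GRs < 250 aa excluded) are aligned with
MAFFT — the field's standard aligner, used directly since it is
deterministic and available — and trees are built by neighbor joining on
maximum-likelihood JTT distances: plain JTT for IRs, JTT+Γ+F for ORs and
GRs, with the gamma shape estimated once per family on the
neighbor-joining starting tree and amino-acid frequencies taken from the
alignment. Node supports are percentages of column-resampled bootstrap
replicates (200 by default) containing each bipartition; the seed is
explicit, so supports reproduce exactly. Trees are rooted on the family's
conserved outgroup lineage (Orco for ORs, sugar receptors for GRs,
IR8a/25a for IRs); when the designated outgroup leaves are not
monophyletic — typical when per-gene outgroup orthologs are used — the
tree falls back to a single-leaf root with a warning.

This distance-based tree replaces a maximum-likelihood topology search.
The downstream contract — bootstrap supports, outgroup rooting, pair
extraction — is unchanged, and neighbor joining is exact on additive
distances (property-tested), but deep relationships in highly saturated
families are estimated less well than by full ML. A related caveat: with
Γ rate heterogeneity and a small estimated shape, distances between
saturated sequences inflate sharply and can destabilise near-star local
topologies; supports flag these nodes, and pair extraction should be read
together with them. For the same reason, rooting on a single conserved
outgroup sequence gives more stable pair extraction than scattering many
deep per-gene outgroup leaves through the tree, whose large net
divergences distort neighbor joining's join criterion.

An orthologue pair is the strictest structure consistent with "pairs":
two leaves from different focal species whose most recent common ancestor
has exactly those two descendants. Each gene can appear in at most one
pair, and the pair inherits the support of its node. Looser
reciprocal-monophyly definitions are deliberately out of scope.

## Codon site models and the selection test

Pairwise codon alignments are built by back-translating the MAFFT protein
alignment (every aligned residue expands to its source codon; columns
containing stop codons are removed with a warning). The substitution
model is GY94 over the 61 sense codons: single-nucleotide changes at rate
`π_y · κ^[transition] · ω^[nonsynonymous]`, uniform codon frequencies by
default (one fewer bank of nuisance parameters, and self-consistent with
the simulator), and the matrix scaled so branch length is expected
substitutions per codon averaged over the ω distribution.

Site models follow the M7/M8 pair: M7 draws ω from beta(p, q),
discretized into K = 10 equal-probability classes represented by their
conditional means; M8 adds one class with ω_s ≥ 1 and weight 1 − p0.
Likelihoods are maximized by bounded quasi-Newton search (bounds
t ∈ [1e-4, 20], κ ∈ [0.1, 20], p, q ∈ [0.05, 50], p0 ∈ [0, 1],
ω_s ∈ [1, 20]) from a fixed set of deterministic starts; the M8 fit is
additionally warm-started at the M7 optimum with p0 = 1, where the two
models coincide exactly, which guarantees `lnL(M8) ≥ lnL(M7)` by
construction rather than by optimizer luck. The likelihood kernel caches
the eigendecomposition of each (κ, ω) rate matrix, which is what makes
hundreds of replicate fits affordable.

The test statistic is `Δ = 2(lnL_M8 − lnL_M7)`, floored at zero, against
χ² with **one** degree of freedom at P < 0.01 by default, although the
conventional count for M7-vs-M8 is two; `df = 2` is available as an
option. Positively selected sites are those with
posterior P(ω > 1) ≥ 0.95 under *both* empirical Bayes variants: NEB
(all parameters at their MLEs) and BEB, which averages NEB-style
posteriors over a 6-points-per-dimension grid on (p0, p, q, ω_s) weighted
by data likelihood under a uniform prior, with branch length, κ and the
rate scaling frozen at the MLEs. The grid uses midpoint quadrature on
each dimension (log-spaced for p, q, ω_s): interior points avoid the
degenerate corners p0 = 0 (every site selected) and ω_s = 1, which would
otherwise dominate weakly informative alignments and *inflate* rather
than shrink posteriors. A pair is called positively selected iff the LRT
passes at 0.01 and at least one site passes both 0.95 cutoffs.

**Known limitation — power.** With only two sequences at moderate
divergence (300 codons, t ≈ 0.5, ω_s = 2, p0 = 0.5), the M7-vs-M8
contrast carries little information: parameter recovery is essentially
unbiased (median ω̂_s ≈ 2.0, median p̂0 ≈ 0.54 across simulation
replicates), but the compound decision rule fires on only a few percent
of truly selected pairs, because Δ rarely clears the 1% χ² point and
single-site posteriors rarely reach 0.95 on one pairwise observation per
site. This mirrors published power analyses of site-model LRTs with very
few sequences. The test suite states the intended operating point and
reports the measured power honestly; on real data, pairs flagged by this
rule are strong candidates (the null error rate is controlled), but
absence of a signal is weak evidence of absence.

## The synthetic-data forge

`forge_genome()` emulates the features the pipeline must survive:
multi-exon genes (2–6 phase-0 GT..AG introns by default, matching the
intron state of the spliced aligner), two 4-gene tandem clusters at 5%
within-cluster divergence placed within 50-kb windows on one strand,
stop-codon pseudogenes (one sense codon mutated to TAA), frameshift
pseudogenes (a 1-bp exonic deletion), 5′-retained partial genes, i.i.d.
uniform intergenic background (GC 50%, so no accidental homology), and
outgroup reference proteins made by substituting ~15% of residues of each
planted gene's source protein — the search must work through cross-species
divergence, and an outgroup ortholog exists for pseudogenes too, since
pseudogenisation happened after the split. Intact genes round-trip
exactly: concatenated exons translate to the recorded protein.

What the forge does **not** emulate: repeats and transposable elements,
GC heterogeneity and codon-usage bias, non-phase-0 or non-canonical
introns, alternative isoforms, assembly gaps, and sequencing error.
Passing the benchmark therefore demonstrates the pipeline's logic —
chaining, splicing, classification, iteration — not robustness to the
full messiness of a real assembly, where manual curation remains part of
the protocol. Similarly, `simulate_codon_pair()` draws each site's ω from
the continuous generating distribution and evolves codons by exact
stochastic simulation of the same GY94 process the likelihood uses — a
matched, not adversarial, test of the estimator.

## Problem sizes and determinism

The shipped validation uses a 2-Mb, 60-gene benchmark genome per seed
(five seeds), 50 constructed spliced-alignment cases, 200 random search
instances, 20 planted orthologue families, and 100 null plus 16
alternative codon-pair replicates of 300 codons — sizes chosen so the
whole suite completes comfortably on a laptop core while leaving every
rate estimate meaningfully resolved. All randomness flows through
explicit seeds (`family_spec(rng_seed=)`, `codon_sim_spec(rng_seed=)`,
`build_tree(seed=)`, `pipeline_config(rng_seed=)`), and seeded runs are
byte-reproducible, including bootstrap supports and every file
`run_pipeline()` writes.
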