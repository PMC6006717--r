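---
title: "Methods: subcellular stoichiogenomics with stoichioprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subcellular stoichiogenomics with stoichioprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichioprot)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic generators do and do not emulate.

## The seven stoichiogenomic characteristics

For a protein sequence of length $L$, the content of element $*$ (one of C,
H, O, N, S) is

$$[*\,\mathrm{content}] = \sum_i w_i \, p_i / L,$$

where $w_i$ is the number of atoms of that element on the side chain of
amino acid $i$ and $p_i$ is the *residue count* of amino acid $i$ in the
sequence. We read $p_i$ as a count, not a frequency: if $p_i$ were already a
fraction, the division by $L$ would double-normalize, and the element
formula would no longer be dimensionally consistent with the charged-residue
fractions below. The result is a per-residue average; e.g. poly-glycine has
hydrogen content exactly 1.

Side-chain atom counts are derived mechanically as the residue formula (free
amino acid minus H$_2$O) minus the peptide-backbone unit C$_2$H$_2$NO, in
neutral (un-ionized) form with no terminal atoms — the quantity is
side-chain-only. Proline gets no special casing: the same subtraction
applies, leaving C$_3$H$_5$. Counts range from 0 to 10 (lysine and arginine
hydrogens). The full table ships both in code (`side_chain_counts()`) and as
an auditable TSV (`inst/extdata/side_chain_elements.tsv`); the test suite
checks every row against an independently encoded table of free-amino-acid
molecular formulas.

The two charged-composition characteristics are plain class fractions:
acidic = (D + E)/L, basic = (K + R + H)/L.

**Nonstandard residues** (B, Z, X, U, O, J and anything else outside the 20
standard codes) are excluded from both the numerator and $L$; sequences with
more than 5% such residues are dropped with a warning. Exclusion avoids
inventing atom counts for ambiguity codes.

**Group means** per (species, location) are unweighted means of per-sequence
values — a short sequence counts as much as a long one. Content ratios
against a reference average (defaults: acidic 0.114955653, basic
0.142665842, overridable) classify a group as `"higher"` (> 1) or `"lower"`
(< 1).

Note one consequence of the chemistry: element and charged contents are
*coupled*. Aspartate and glutamate carry two side-chain oxygens, the basic
residues carry one to three nitrogens. Any shift in charged-residue usage
therefore moves element contents as well; a nitrogen signal in a
basic-enriched compartment is expected, not incidental. This matters when
interpreting screens (below). One caveat: tryptophan's ring nitrogen also
contributes, so nitrogen is not carried by amide and basic side chains
alone; the implementation follows the chemistry.

## Annotation handling

The canonical input is a FASTA file plus a four-column TSV (`accession`,
`species`, `location`, `experimental`) — Swiss-Prot flat-file parsing is
deliberately out of scope, though the TSV is trivially produced from such
records. Processing steps:

1. **Evidence filter**: keep proteins with at least one experimentally
   evidenced location; drop their predicted location rows.
2. **Label normalization**: raw phrases map onto the closed nine-label set
   {cytoplasm, cytoskeleton, endoplasmic reticulum, extracellular, golgi,
   membrane, mitochondria, nucleus, transmembrane} through an editable
   mapping table; a phrase containing a transmembrane topology term maps to
   `transmembrane`, other membrane phrases to `membrane`. Unmapped labels
   drop with a warning; a protein whose whole label set is unmapped is
   *excluded*, not errored.
3. **Cytoskeleton collapse**: a protein co-annotated cytoskeleton + nucleus
   or cytoskeleton + cytoplasm is recorded as cytoskeleton only (the rule
   generalizes to sets containing all three).
4. **Single/dual partition**: exactly one canonical location = single; two
   or more = dual (counted once, listed under each location); none =
   excluded. Every protein lands in exactly one class.
5. **Species filter**: species with *strictly more* than `min_count`
   proteins are kept (default 300; the threshold is configurable and the
   strict inequality is our reading of "larger than"). We apply it after
   evidence filtering and before location-category pruning; the ordering is
   not forced by anything upstream, so it is a documented choice.

## Isoelectric points

Net charge at pH $p$ follows the Henderson–Hasselbalch model: positive
groups (N-terminus, H, K, R) contribute $n/(1 + 10^{p - pK_a})$, negative
groups (C-terminus, D, E, C, Y) contribute $-n/(1 + 10^{pK_a - p})$. The
default pKa values are the Bjellqvist set used by the ExPASy Compute pI
tool: side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
C-terminus 3.55; N-terminus 7.5 with residue-dependent overrides (A 7.59,
M 7.00, S 6.93, P 8.36, T 6.82, V 7.44, E 7.70). Positional side-chain
adjustments for terminal residues (present in the fullest version of the
Bjellqvist table) are not applied; the whole set is a swappable `pka_set()`
object. Cysteine and tyrosine are ionizable here even though they are not
"charged" residues in the composition classes — pI and charged content are
distinct computations.

The charge is continuous and non-increasing in pH, and the termini guarantee
a sign change on $[0, 14]$, so the isoelectric point is found by bisection,
stopping when the bracket is narrower than $10^{-3}$ pH units or the
absolute charge falls below $10^{-4}$ (both configurable). The suite checks
the root against a dense grid scan (step $10^{-4}$).

For a protein pair the complementarity statistic is
$\delta = PI_{max} - PI_{min} \ge 0$, symmetric under swapping the pair.
Control sets of non-interacting pairs are drawn uniformly without
replacement over unordered pairs, excluding self-pairs and any known
interaction (order-insensitive), reproducibly under a seed.

## Prokaryotic analogs

Putative 1:1 orthologs are bidirectional best hits: $(a, b)$ is kept iff $b$
is $a$'s best hit in one direction and $a$ is $b$'s best hit in the other.
The search engine is pluggable:

* **built-in**: Smith–Waterman local alignment (BLOSUM62, affine gaps,
  open 11 / extend 1) scored by Biostrings, converted to bit scores and
  E-values with Karlin–Altschul statistics at the standard gapped BLOSUM62
  parameters ($\lambda = 0.267$, $K = 0.041$), database size = summed target
  length. Adequate for desk-scale proteomes and fully deterministic.
* **blastp**: an adapter shelling out to BLAST+ for real-scale runs.

Desk-scale results must not depend on the engine; the tests check the
built-in engine against an independent dynamic-programming implementation.
Best-hit ties break by higher bit score, then lower E-value, then
lexicographically smaller target id — a documented house rule. The default
E-value cutoff is $10^{-5}$ ($10^{-10}$ for mapping queries onto structure
chains).

Genomes pass a mesophile filter: growth temperature within 15–50 °C,
bounds inclusive (configurable); genomes lacking a temperature drop with a
warning. In the per-location comparison, analog means pool *per occurrence*
by default — a protein matched in $k$ genomes contributes $k$ analog
sequences — with per-genome averaging available, since either convention is
defensible and they differ when genome sizes are uneven. A location with no
analog pairs yields an NA row, not an error.

## Structure interfaces

Curated interface databases mix hydrogen-bond and non-bonded contact
criteria whose exact parameters are not published, so the package defines
the interface geometrically: residue $r$ of chain A is interfacial iff any
heavy atom of $r$ lies within a cutoff (default 4.5 Å, configurable) of any
heavy atom of chain B, and symmetrically. Precomputed interface-residue
tables are accepted as direct input to bypass the geometric definition.
Parsing keeps ATOM records of standard residues in the first model, altloc
'' or 'A', no hydrogens, no waters or HETATM.

Interface composition reports, per interface, the fractions of Glu, Asp,
Lys, Arg, His and the acidic/basic classes. Because it is not obvious
whether summary rows should average per-interface fractions or pool residues
across interfaces, both are computed; per-interface averaging is the
default summary. The interface-vs-remainder comparison emits paired rows per
complex (a complex whose every residue is interfacial gets an NA remainder
row; with no interface the remainder equals the whole complex).

## Statistics: the dual criterion

Two-sample comparisons run Mann–Whitney *and* Kolmogorov–Smirnov; a
difference is significant only when both p-values fall below $\alpha$
(default 0.05). When the tests disagree, the verdict is "not significant"
and the believed direction follows Mann–Whitney, the more robust of the two;
the discrepancy is recorded in the report. The Mann–Whitney p-value is exact
when $\min(n) \le 8$ and there are no ties, otherwise a normal approximation
with tie correction — the switch is configurable and an `exact` override is
available. One-tailed alternatives are supported for directional claims
(note that R's `ks.test` alternative refers to CDF ordering, which the
package maps back to location language). Degenerate all-tied inputs return
p = 1 with a warning.

Proteome-wide location screens test each location's per-sequence values
against the pooled remaining locations (default) or against every other
location (`all_pairs`). **No multiple-testing correction is applied** — the
screen instead tightens its default $\alpha$ to 0.01. Users scanning many
characteristics and locations should keep that in mind.

One property of one-vs-rest screening deserves emphasis: if a single
location is enriched, every *other* location also differs significantly from
its own pooled rest at large $n$, because that rest contains the enriched
cell — those flags point in the *low* direction. Enrichment recovery should
therefore be read off the significantly *elevated* flags (the report's
`direction` column), or from all-pairs mode.

Multi-group comparisons use one-way ANOVA followed by Tukey HSD.
Relation-table tallies count KEGG-style relation types (activation,
binding/association, complex, indirect effect, inhibition, phosphorylation,
dissociation, dephosphorylation, state change), with unknown types tallied
under "other", and report percentages to one decimal.

## The synthetic generators

The generators emit exactly the formats the pipeline consumes (FASTA,
annotation TSV, pair TSV, PDB files) plus closed-form truth manifests, so
every stage is testable without downloads. They are pure functions of
(spec, seed).

**Sequences** are i.i.d. residues from per-location frequency vectors: a
uniform baseline (0.05 per amino acid — chosen over empirical frequencies so
closed-form expectations stay simple) plus named additive boosts. Boost mass
is compensated *proportionally from the 14 amino acids that are neither
charged nor cysteine*, so an acidic boost leaves expected basic content
untouched and vice versa. That orthogonality is what makes parameter
recovery clean for the charged characteristics; element contents still move
with any boost (chemical coupling, above), which is why recovery is asserted
within the charged pair rather than across all seven characteristics. The
default study conditions: cytoskeleton acidic +0.05, nucleus basic +0.05,
extracellular cysteine +0.03; lengths log-normal($\mu = 5.5$,
$\sigma = 0.4$) clamped to [50, 5000] (arbitrary but documented; mean ≈ 270
residues); dual-location fraction 0.2, dual residues drawn from the mean of
the two locations' vectors.

**PPI pairs**: a complementary pair couples an acidic-boosted sequence
(+0.10, expected pI well below 7) with a basic-boosted one (expected pI
above 7); background pairs are two baseline sequences. Class counts follow
the spec exactly. Under full complementarity the pair-member pI distribution
is bimodal with a near-empty neutral band (the tests assert < 5% of members
in [6.8, 7.2]); under zero complementarity the PImin/PImax distributions
overlap heavily.

**Complexes**: CA-only two-chain structures; chain A runs along the x-axis
at 3.8 Å spacing, the first `interface_size` residues of chain B sit 4.0 Å
from their chain-A counterparts and the rest are displaced 100 Å away, so
exactly the designated residues are interfacial at any cutoff in
(4.0, $\sqrt{3.8^2 + 4.0^2}$ ≈ 5.5) — which brackets the 4.5 Å default.
Interface residues draw with Glu frequency boosted by `glu_delta` (default
+0.04, the scale of the contrast the interface analysis is meant to detect).

What the generators do *not* emulate: realistic amino-acid frequencies,
residue autocorrelation and domain structure, length–composition
correlations, real fold geometry (the toy complexes are chemically and
geometrically minimal), evolutionary relatedness between "analog" proteomes
(tests construct analogs by point mutation), and annotation noise. Passing
tests therefore demonstrate correctness of the computations and
recoverability of injected signals under clean conditions — not that real
proteomes show these signals.

## Statistical calibration of the acceptance checks

Because the dual criterion's two tests are strongly correlated, its
per-comparison false-positive rate is close to $\alpha$ itself, not
$\alpha^2$. A screen over 8 (characteristic, location) cells at
$\alpha = 0.01$ therefore produces at least one false flag in roughly 5% of
datasets. The recovery check accordingly runs over ten replicate datasets:
the injected flag must be recovered in every replicate, and the flag set
must be *exactly* the injected one in at least eight of ten. A companion
null simulation (200 replicate screens with no boosts) checks the
per-comparison false-positive rate stays at or below $\alpha$.

Problem sizes used by the tests and the acceptance script: 1000 random
sequences for the composition oracle; 100 sequences for the pI grid-scan
oracle; 8-vs-8 toy proteomes for the alignment oracle; 500 sequences per
cell for recovery; 250 + 250 pairs for the PPI contrast; 100 + 100 complexes
for the interface contrast. These sizes give the checks comfortable power
while keeping a full run to a few minutes on one CPU.

## Known limitations

* The pI model is sequence-only: no structure-based pKa shifts, no
  positional side-chain adjustments at termini; values can differ from
  other calculators by a few tenths of a pH unit depending on their pKa
  tables.
* Karlin–Altschul parameters are fixed at the standard gapped BLOSUM62 11/1
  values rather than estimated per scoring system; E-values on toy databases
  are indicative, not calibrated.
* The geometric interface definition approximates curated contact lists; a
  single distance cutoff cannot reproduce hydrogen-bond-specific criteria
  bit-exactly, which is why precomputed interface tables are accepted.
* mmCIF structures, solvent-accessibility interface definitions and
  energy-based analyses are out of scope.
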