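---
title: "Methods: a genome-wide VQ family survey for hexaploid genomes"
author: "vqsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide VQ family survey for hexaploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices
behind `vqsurvey`, in the spirit of the methods sections of the mature
Bioconductor analysis packages. It states no empirical result beyond what
the package's own tests and `scripts/acceptance.R` compute.

## The survey problem

VQ proteins are short plant transcriptional cofactors defined by a single
conserved decamer, FxxhVQxhTG, where `x` is any residue and `h` a
hydrophobic one. In hexaploid wheat-like genomes each gene is expected in
up to three homoeologous copies on the A, B and D subgenomes, so a family
survey has two intertwined layers: per-gene features (motif variant,
protein properties, structure, promoter content) and group-level
features (retention ratios, homoeolog-averaged expression). `vqsurvey`
implements both layers as composable functions plus one orchestration
call, `run_survey()`.

## Motif identification

The scan is a literal decamer match, `F,x,x,x,V,[QH],x,h,T,G`, reported
as *canonical*; windows that satisfy the first eight positions but do not
end in `TG` are reported as *non-canonical* — this is how the observed
VMA-type terminus is captured without opening the scan to arbitrary
8-mers. The hydrophobic set defaults to {A, V, L, I, M, F, W, Y, C},
which covers the position-8 residues seen in published family alignments
(L, F, I, V) plus the standard hydrophobics; it is a function argument,
not a constant. `X` never satisfies a constrained position. This
deterministic scan deliberately replaces profile-HMM searching: it needs
no external binaries or profile downloads, is exactly reproducible, and
targets the same biological signal. The cost is that true family members
whose motif degrades beyond the pattern would be missed — a profile
search remains the right tool for distant-homolog discovery.

## Protein descriptors

* Molecular weight: sum of average (not monoisotopic) residue masses
  plus one water, the ExPASy ProtParam convention.
* GRAVY: mean Kyte–Doolittle hydropathy; negative means hydrophilic.
* Aliphatic index: Ikai's `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))`
  on mole percents; values ≥ 65 are called thermostable.
* Instability index: Guruprasad's `(10/L) Σ DIWV(aa_i, aa_{i+1})` with
  the published 20×20 dipeptide table shipped as a data constant; > 40 is
  called unstable.
* Isoelectric point: root of the Henderson–Hasselbalch net charge
  (N-terminus, K, R, H positive; C-terminus, D, E, C, Y negative) by
  bisection on pH ∈ [0, 14] to |charge| < 10⁻⁴ (≤ 100 iterations;
  convergence is guaranteed because charge is monotone in pH). The pKa
  set defaults to the published EMBOSS values because they are explicit
  and unambiguous; ExPASy's internal set differs slightly, so pI values
  may differ from ExPASy output by roughly 0.1–0.3 pH units. The
  categorical thresholds (basic pI > 7, unstable > 40, thermostable
  ≥ 65, hydrophilic GRAVY < 0) follow the conventions of published
  family surveys.

## Coordinates, promoters, structure

All coordinates are 1-based inclusive (the GFF3 dialect). The promoter
is anchored at the translation start — the first CDS base — not the
transcript start: for a plus-strand CDS starting at `s`, the window is
`[s − L, s − 1]` with L = 1500 bp by default; minus-strand genes take
the reverse complement of the mirrored window. Windows are truncated at
chromosome edges rather than padded, so a promoter may be shorter than
requested; padding would fabricate sequence. For multi-isoform genes the
mRNA with the longest total CDS is the representative model. Intron
counts are computed on transcript exons (introns = exons − 1), the GSDS
convention, so UTR-containing exons count as exons, not as CDS segments.

## Homoeolog triads

Groups are *supplied* (by the generator's manifest or any upstream
orthology call), not inferred: similarity-based grouping is a research
problem of its own and any inference here would be arbitrary. Retention
categories depend only on the per-subgenome member counts and are
symmetric in A/B/D: (1,1,1) triad; exactly one count > 1 with the others
1, homoeolog-specific duplication; exactly one count 0 with the others 1,
single-homoeolog loss; a lone gene, orphan; everything else — including
mixed cases like (2,0,1) — OTHER. Percentages are over genes (not
groups), printed to one decimal with half-up rounding, matching how such
tables are normally typeset; the categories of a 113-gene family can
therefore sum to 100.1.

## Duplication and Ka/Ks

Candidate pairs are aligned globally at the protein level
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5) and the alignment
is back-translated to codons, so gaps stay in whole-codon units. This
replaces local BLASTN search: the 75/75 duplication rule only needs
coverage and identity, which a deterministic global alignment provides
reproducibly and without external binaries. Coverage is the aligned
(non-gap) length over the longer CDS; identity is counted on nucleotides
over non-gap columns; both thresholds are strict (`> 0.75`). In
`find_duplications()` two sound screens precede the full alignment: the
CDS length ratio (which upper-bounds attainable coverage) and a
vectorized protein alignment score (unrelated proteins score far below
zero under global BLOSUM62; near-identical duplicates far above — the
default cutoff of 0 is generous on both sides), after which the full
codon alignment decides.

Tandem vs segmental is decided by locality: same chromosome and either
≤ 5 intervening annotated genes or midpoints ≤ 200 kb apart means
tandem. Neither constant is canonical in the literature; these defaults
are common plant-genomics practice and both are exposed as arguments.

Ka/Ks follows classic Nei–Gojobori (1986) counting. Synonymous site
counts per codon exclude stop-codon mutations from the denominator (the
MEGA / KaKs_calculator NG convention); S is averaged over the two
sequences and N = 3·codons − S. Differences are partitioned by
equal-weight averaging over all minimal substitution pathways that avoid
stop codons; if every pathway is stop-blocked (possible only in rare
constructed cases, never for the generator's fixtures) the average falls
back to all pathways. Proportions are Jukes–Cantor corrected,
`d = −(3/4)·ln(1 − (4/3)p)`, undefined (NA) at p ≥ 3/4; Ka/Ks is NA when
Ks is 0 or either rate is undefined. The test suite checks the
implementation against an independent pathway-enumeration oracle on 200
random codon pairs to 10⁻⁹ and asserts exact `ka = 0` for
synonymous-only planted divergence.

## SSR mining

Perfect tandem repeats of unit length 1–6 with MISA's default minimum
counts (10, 6, 5, 5, 5, 5) are found by a shift-comparison run-length
scan; `N` never matches, so it cannot start or extend a repeat. A run
reportable under several unit lengths is reported once at the smallest
unit, enforced via unit primitivity (an `AAAA…` run is mono, never di
`AA`). Trailing partial units are truncated, so `end − start + 1 =
unit × count` always. Repeats are perfect only, and motifs are reported
as found — no canonical rotation or reverse-complement folding — which
matches per-locus SSR tables. Compound SSRs merge simple records
separated by ≤ 100 bp (MISA's default interruption), transitively.

## Promoter cis-elements

The catalog maps element names to IUPAC consensus strings and categories
(WRKY-binding / hormone / stress / development). Only the W-box entry,
TTGACC/TTGACT, is a fixed literature consensus; the remaining defaults
are PlantCARE-style strings chosen as reasonable stand-ins and are fully
overridable, so any downstream comparison against a specific database
should supply its own catalog. Scanning is both-strand by default (a
flag disables it), all overlapping occurrences count, and an `N` in the
sequence matches nothing. A palindromic consensus reports one hit per
strand at the same offset.

## Phylogeny

Multiple sequence alignment is out of scope — the stage accepts any
aligned FASTA; `align_center_star()` exists only to build small fixtures
and says so in its documentation. Distances are p-distances with
pairwise deletion (columns with a gap or X in either row are skipped);
a Poisson-corrected variant is provided because distance-model defaults
differ between programs. Neighbor joining is the classic Saitou–Nei
iteration on `Q(i,j) = (n−2)d(i,j) − Σd(i,·) − Σd(j,·)`; Q ties are
broken by the lexicographically smallest pair of cluster representative
names so the output is order-independent; negative branch-length
estimates are clamped to zero and flagged (the MEGA convention).
Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and reports the percentage of replicates
containing each original bipartition; an alignment with no variable
columns is flagged degenerate rather than given meaningless supports.
Subgroup assignment gives each query leaf the label of the smallest
clade (over all rootings) containing it and at least one labeled
reference, provided the labels in that clade agree; conflicts yield
UNASSIGNED rather than a guess.

## Expression

Homoeolog averaging is the arithmetic mean of member TPMs per column,
so group totals are conserved. The expression flag reads "tpm < 1 is
unexpressed" strictly: exactly 1.0 counts as expressed. Heatmap values
are `log2(tpm + 1)`. Relative qPCR quantification is 2^−ΔΔCt with ΔCt
averaged over biological replicates (the aggregation is rarely stated in
papers; the replicate mean is the least-surprising choice), the control
record being the designated control timepoint of the same gene and
condition; the control's RQ is exactly 1 by construction, and the whole
statistic is invariant to any constant shift applied to both Ct columns.
Both RQ and log2(RQ) are emitted since heatmap conventions vary.

## The synthetic fixture and what it shows

`generate_survey_data()` builds a toy 21-chromosome hexaploid genome
whose defaults *are* the published family structure of the wheat VQ
survey: 113 genes in 40 homoeolog groups (25 triads / 75 genes, 4
duplication groups / 17 genes, 8 loss groups / 16 genes, one
other-ratio group planted as (0,2,1), 2 orphans), 103/113 intronless,
the observed motif-variant census (LTG 86, FTG 11, ITG 3, VTG 8, VH-core
VTG 4, VMA 1), 28 SSRs in 25 genes (75.0% tri, 7.1% di), a W-box in 55
of 113 promoters, and 30 of 40 groups expressed. Where the underlying
survey leaves a quantity unstated, one realistic value was fixed once:
founder proteins of 120–240 residues (the family's typical ~80–570 range
centers near 190), 220-bp 3′ UTRs as SSR planting ground, 150-bp introns,
200-bp intergenic spacers, five duplication pairs (two tandem, three
segmental) with 0–10 planted substitutions each, TPM columns in four
organ classes, and Ct noise of SD 0.1 cycles across three replicates.

Background sequence is rejection-sampled: any window matching a planted
pattern (or its reverse complement) is re-randomized until clean, which
keeps base composition uniform, and every planting is verified by an
exact recount before the fixture is accepted. Degenerate catalog
patterns such as MYC's CANNTG are *not* cleaned from background — a
1.5-kb window free of CANNTG is essentially unsamplable and biologically
unreal — so recovery guarantees cover the planted elements only.
Codon substitutions in duplication pairs are planted one per codon,
outside the motif, never creating stops, so the synonymous/nonsynonymous
class of each change is unambiguous and `ka = 0` (resp. `ks = 0`) holds
exactly for syn-only (nonsyn-only) pairs.

The generator emulates feature *placement*, not genome realism: no
transposons, no GC heterogeneity, no UTR introns, homoeologs are
unrelated in sequence (only the five duplication pairs are similar), and
expression noise is a smooth weight vector around the group mean.
Passing the recovery suite therefore demonstrates that the pipeline's
logic is exact on unambiguous input; it does not certify performance on
real genomes, where motif decay, nested genes, imperfect repeats and
fragmented scaffolds add failure modes this fixture deliberately lacks.

## Problem sizes and determinism

The shipped tests run the full pipeline on the 113-gene default fixture
(about a megabase of genome, one CPU, roughly a minute of alignment
work) and keep simulation-based property suites at sizes where each file
finishes in seconds: 200 oracle-checked Ka/Ks pairs of ≤ 60 codons, 100
random additive 8-taxon NJ instances, 10³ random kilobase SSR sequences.
Everything downstream of `survey_config(seed = …)` is deterministic:
regenerating with the same seed is byte-identical, and `run_survey()`
contains no randomness at all.
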