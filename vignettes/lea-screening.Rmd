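---
title: "Screening nematode ESTs for LEA-like hydrophilic proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nematode ESTs for LEA-like hydrophilic proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leascan)
```

## The biological question

Anhydrobiotic nematodes such as *Aphelenchus avenae* survive near-complete
desiccation, and part of their preparation for the dry state is
transcriptional: genes encoding highly hydrophilic, intrinsically
disordered proteins — notably the late embryogenesis abundant (LEA)
family — are strongly upregulated during preconditioning. Candidate LEA
transcripts in an EST (expressed sequence tag) collection can be
recognised purely from sequence, because Group 3 LEA proteins share a
distinctive set of hallmarks:

* extreme hydrophilicity — a grand average of hydropathy (GRAVY) far
  below that of ordinary globular proteins;
* predicted native disorder — they fall on the unfolded side of the
  charge–hydropathy plane;
* an 11-residue periodicity of lysines ("K11"), often as interlaced
  runs in different phases;
* absence of cysteine and tryptophan.

`leascan` codifies these hallmarks into an explicit, testable pipeline
that runs from raw EST nucleotide sequences to a per-record
classification, together with a seeded simulator that generates ESTs
with known ground truth so every stage can be validated end to end.

## EST anatomy and the pre-processing model

A full-length nematode EST in mRNA sense is modelled as

```
[spliced leader][5' UTR][ATG ... stop][3' UTR][polyA tail]
```

**PolyA trimming.** `trim_polya()` removes the maximal trailing
adenosine run of at least `min_run` (default 8) bases, tolerating up to
one non-A base per 10 trailing bases to absorb single-pass sequencing
noise. The tail must begin with an A, so trimming never bites into the
3' UTR. The operation is total and idempotent; trimming an all-A record
yields an empty sequence with a warning rather than an error.

**Spliced-leader detection.** Nematode mRNAs frequently carry a ~22 nt
leader trans-spliced onto their 5' end. `detect_sl()` compares every
catalogue leader against the EST start at offsets 0–3 and accepts at
most 2 mismatches, ranking hits by (mismatches, offset, catalogue
order). The thresholds are a policy choice, not a published constant:
a 22-mer at two mismatches has a negligible chance of matching random
sequence, while the small offset allowance tolerates residual vector or
adapter bases. The default catalogue carries the twelve *A. avenae*
leaders (SL1a–d and Variants 1–8) plus the canonical *C. elegans* SL1
and SL2; Variant 8 is stored without the leading alignment gap of its
source table (21 nt), preserving the alignment intent.

**Family assignment.** `classify_family()` globally aligns a variant
leader against canonical SL1 and SL2 and assigns the family with the
higher score. The scorer is the package default (match +1, mismatch −1,
gap −1). Before freezing this default we confirmed, against an
exhaustive enumeration of the alignment space, that it assigns Variants
1–4 to SL1 and Variants 5–8 to SL2 — the qualitative split the leaders
were described with. Equal scores return `"ambiguous"` rather than an
arbitrary pick.

**ORF extraction.** `find_longest_orf()` scans the three forward frames
(ESTs from an oligo-capped, oriented library are mRNA-sense; reverse
scanning is available behind `forward_only = FALSE`) for ATG-initiated,
stop-terminated frames and returns the longest, breaking ties by the
smaller start. Coordinates are 1-based and inclusive, with `end` on the
last base of the stop codon, so printed residue positions can be
compared directly. Up to `readthrough_uga` internal UGA codons are
translated as selenocysteine (`U`) before UGA is treated as stop —
the mechanism by which selenoprotein mRNAs such as some glutathione
peroxidases extend their reading frame. UAA and UAG always terminate.
ORFs running off the sequence end are considered only with
`allow_open_end = TRUE`, because single-pass ESTs are frequently
3'-truncated and an open frame is weaker evidence.

## Physicochemical profiling

Two hydropathy systems deliberately coexist:

* **GRAVY** uses the *Eisenberg consensus* scale. The score is the
  plain arithmetic mean of per-residue values; unknown residues (`X`)
  are excluded from numerator and denominator. The hydrophilicity
  threshold used downstream, −0.43, is the GRAVY of bovine serum
  albumin — an ordinary, soluble, globular reference protein.
* **Charge–hydropathy coordinates** use the *Kyte–Doolittle* scale
  rescaled to [0, 1] by \((h + 4.5)/9\), the convention of the
  disorder predictors this family of methods descends from. The mean
  scaled hydropathy \(\langle H\rangle\) smooths per-residue values
  with a centred window (default 5 residues, truncated at the ends)
  before averaging; the mean net charge
  \(\langle R\rangle = |(\#K + \#R) - (\#D + \#E)|/L\) counts only the
  four residues that are essentially fully charged at neutral pH
  (histidine and the termini are excluded, matching common
  charge–hydropathy-plot practice).

Molecular weight uses average (not monoisotopic) residue masses plus
one water; selenocysteine has its own mass entry. The isoelectric point
is the zero of the Henderson–Hasselbalch net charge, found by bisection
on pH 0–14 to far below the 0.01 pH units it is reported at. The pKa
set defaults to the EMBOSS table (a Lehninger set is also embedded);
published pI values for the same protein can differ by a few tenths of
a unit across pKa sets, which is why pI comparisons in this domain
should carry a tolerance of about ±0.3.

## Disorder classification

A protein at \((\langle H\rangle, \langle R\rangle)\) is compared with
the empirical boundary

\[ \langle H\rangle_b = \frac{\langle R\rangle + 1.151}{2.785} \]

and called **unfolded** when \(\langle H\rangle < \langle H\rangle_b\).
Points exactly on the boundary are called folded — a documented
tie-break; the boundary itself was fitted to separate known folded from
natively unfolded proteins, so on-the-line points carry no information
either way.

The windowed counterpart, `foldindex_profile()`, applies the same
relation per window as an unfoldability index
\(I = 2.785\,\langle H\rangle_w - |\langle R\rangle_w| - 1.151\),
with a default window of 51 residues (the conventional server default;
shorter proteins use the whole sequence as one window). Negative
indices predict disorder, and the percent of residues with negative
index is the protein's percent disorder. With a whole-sequence window
and unsmoothed coordinates the index sign and the whole-protein
classification agree by construction — one of the closed-form limits
the test suite asserts. Machine-learned disorder predictors are a
different family of methods and are deliberately not reimplemented
here; percent-disorder values from such tools are accepted as plain
numbers by the classifier instead.

## Periodicity

`find_periodic_runs()` reports, for each residue type, every *maximal*
arithmetic chain of occurrence positions with common difference
`period`: in the peptide `GAGPG`, glycine occupies positions 1, 3 and 5
and so recurs with period 2. Chains in different phases (position
modulo period) are reported separately; this is exactly what makes
"interlaced" K11 runs visible as two chains of three lysines rather
than one diffuse signal. Maximality means the residue does not occur at
`first − period` or `last + period`; whether sub-runs of a longer run
should also be reported is unknowable from the method's description, so
maximal-only is the documented choice, and the brute-force oracle in
the tests enumerates maximal progressions the same way. Matching is by
exact residue identity; a residue-class mode (e.g. K/R) is noted as
future work. The default minimum run length is 3.

## The LEA rule cascade

The published identification of LEA candidates is narrative; `leascan`
codifies it as an explicit cascade over computed evidence, with every
threshold exposed in `lea_criteria()`:

| label | condition |
|---|---|
| `group3_lea` | GRAVY < −0.43 **and** unfolded **and** ≥ 1 period-11 lysine run **and** no C/W |
| `lea_like` | GRAVY < −0.43 **and** unfolded |
| `hydrophilic_novel` | GRAVY < −0.43 **or** percent disorder > 50 |
| `not_lea_like` | otherwise |

Inequalities are strict on both thresholds, following the convention
the thresholds were stated with; a protein at GRAVY exactly −0.43 or
disorder exactly 50% is *not* flagged. Compositional-clustering
evidence (an external published tool) is not part of the cascade and
appears in the evidence table as "not evaluated". The cascade is
monotone: the `group3_lea` conditions imply the `lea_like` conditions,
which imply the `hydrophilic_novel` disjunction, so exactly one label
applies.

## What the synthetic generator does and does not emulate

The simulator exists so that the pipeline can be validated without any
external sequence data, with ground truth known by construction.

* `make_lea_like_protein()` samples a charge-rich hydrophilic
  background (E, D, Q, N, R, S, T, G; no lysine, cysteine or
  tryptophan) and plants exactly `n_k11_runs` period-11 lysine chains
  of length 3 in distinct phases. Because lysine occurs nowhere else,
  the planted chains are provably maximal and exactly countable. The
  background is resampled (bounded retries) until GRAVY is below −1.0,
  the charge–hydropathy call is unfolded with a 0.02 margin, and
  percent disorder exceeds 55 — every generated record sits strictly
  inside the classifier thresholds (GRAVY margin ≥ 0.2, disorder
  margin ≥ 5 points), so classification recovery must be exact rather
  than borderline-flaky.
* `make_globular_protein()` mirrors this on the folded side
  (hydrophobic pool, GRAVY > 0.2, folded with margin).
* `make_est()` back-translates a protein with uniformly sampled
  synonymous codons (no organism codon-usage table is applied, as none
  is established for this species), inserts TGA for selenocysteine
  residues, appends a TAA stop, and wraps the CDS in a catalogue
  leader, random UTRs and a polyA tail. The assembled record is
  re-checked — the longest ORF must be exactly the planted one and
  polyA trimming must recover exactly the planted tail length — and
  UTRs are resampled on failure.
* Decoy records are random sequence verified to contain no leader, no
  tail and no ORF of ≥ 20 codons.

All generators consume R's RNG only through `sample()`, under a seed
that is restored afterwards, so a collection is a pure function of
`(spec, seed)` and two calls produce byte-identical FASTA output.

What the simulator does **not** model: sequencing error inside the CDS,
chimeric reads, quality scores, truncated (partial) ORFs, codon-usage
bias, and real UTR composition. Passing round-trip tests therefore
demonstrate that the pipeline's stages are mutually consistent and
recover planted structure exactly; they do not demonstrate robustness
to the error modes of real single-pass ESTs.

## Numerical and design choices

* Coordinates are 1-based and inclusive throughout, for direct
  comparison with printed residue positions.
* The Needleman–Wunsch aligner uses linear gap scoring with a
  deterministic traceback (diagonal preferred over up over left), so
  reports are byte-reproducible. Percent identity is matches over
  alignment columns. Identities printed by other alignment tools with
  unknown scoring should be treated as indicative when compared with
  this scorer's output.
* The pI bisection terminates at 10⁻⁴ pH units; `net_charge` at the
  returned pI is below 0.01 in magnitude.
* Degenerate inputs are handled totally where the operation is total
  (polyA trimming, detection returning `NULL`) and with named errors
  where a result would be meaningless (mass with `X` residues, GRAVY
  of an all-`X` protein, alphabet violations naming the record).
* Batch characterisation (`characterise()`) never aborts on a bad
  record: failures become rows with a `status` column.
* Validation problem sizes: the round-trip acceptance property runs on
  200 simulated ESTs; alignment optimality is checked exhaustively on
  short pairs and against an independent aligner on 1000 random pairs
  up to length 8; periodicity is checked against brute-force
  enumeration on sequences up to length 40 and periods up to 5. These
  sizes give full coverage of the properties at small scale while
  keeping the default test run fast.

## Known limitations

* The charge–hydropathy family is the only disorder predictor
  implemented; proteins with locally alternating charge can be
  misjudged by purely compositional methods.
* SL detection assumes the leader is at (or within 3 bases of) the 5'
  end; internal chimeric leaders are not searched.
* The LEA cascade distinguishes Group 3 only through the K11
  criterion; Groups 1 and 2 are not separately modelled.
* pI and Mr depend on the chosen pKa set and average masses; both are
  selectable/documented, but cross-tool comparisons need tolerances.
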