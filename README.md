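# leascan

Screening nematode ESTs for LEA-like hydrophilic protein candidates.

## The problem

Anhydrobiotic nematodes (e.g. *Aphelenchus avenae*) survive extreme
desiccation, and transcripts upregulated while they precondition for the
dry state are enriched for genes encoding highly hydrophilic,
intrinsically disordered proteins — notably the late embryogenesis
abundant (LEA) family. Candidate LEA transcripts can be recognised
directly from EST sequence by a set of hallmarks: extreme hydrophilicity,
predicted native disorder, 11-residue lysine periodicity (the Group 3
LEA signature), and absence of cysteine and tryptophan.

`leascan` is for sequence analysts who have EST/cDNA collections from
such organisms and want a reproducible, fully tested pipeline from raw
nucleotide records to a per-EST characterisation and classification.

## What it computes

For each EST (mRNA sense, possibly with a trans-spliced leader and a
polyA tail):

1. **polyA trimming** — maximal trailing A-run (≥ 8 nt, ≤ 1 non-A per
   10 trailing bases).
2. **Spliced-leader detection** — best prefix match against a catalogue
   of 21–23 nt nematode leaders (twelve *A. avenae* leaders plus the
   canonical *C. elegans* SL1/SL2), at ≤ 2 mismatches and ≤ 3 bases
   offset; variant leaders are assigned to the SL1 or SL2 family by
   global alignment (Needleman–Wunsch, match +1 / mismatch −1 / gap −1).
3. **ORF extraction** — longest ATG-initiated, stop-terminated forward
   frame; up to *k* internal UGA codons may be read as selenocysteine
   (U), the read-through that extends selenoprotein frames.
4. **Physicochemical profile** — GRAVY on the Eisenberg consensus scale
   (mean per-residue hydropathy), molecular weight (average masses), pI
   (Henderson–Hasselbalch bisection, EMBOSS pKa set), and the
   charge–hydropathy coordinates: mean scaled hydropathy
   ⟨H⟩ (Kyte–Doolittle rescaled by (h+4.5)/9, window-smoothed) and mean
   net charge ⟨R⟩ = |(#K+#R) − (#D+#E)|/L.
5. **Disorder call** — unfolded iff ⟨H⟩ < ⟨H⟩ᵦ = (⟨R⟩ + 1.151)/2.785,
   plus a FoldIndex-style windowed profile
   I = 2.785⟨H⟩w − |⟨R⟩w| − 1.151 with percent disorder = % residues
   with I < 0.
6. **Periodicity** — maximal arithmetic chains of a recurring residue
   (in `GAGPG`, G recurs with period 2); period-11 lysine chains are
   the K11 signature.
7. **LEA classification** — a strict rule cascade:
   `group3_lea` (GRAVY < −0.43 ∧ unfolded ∧ K11 ∧ no C/W) →
   `lea_like` (GRAVY < −0.43 ∧ unfolded) →
   `hydrophilic_novel` (GRAVY < −0.43 ∨ disorder > 50%) →
   `not_lea_like`.

A seeded simulator (`make_est_collection()`) generates ESTs with
ground-truth manifests so the whole pipeline is testable without any
sequence downloads.

## Worked example

```r
library(leascan)

col <- make_est_collection(6, seed = 3)   # simulated ESTs + manifest
rep <- characterise(col$sequences)
rep[, c("id","status","sl_name","orf_aa","gravy","uversky_class",
        "percent_disorder","k11_lysine_runs","label")]
#>          id status  sl_name orf_aa  gravy uversky_class percent_disorder
#> 1 synth0001     ok     SL1c    119 -1.322      unfolded              100
#> 2 synth0002     ok Variant2    136  0.984        folded                0
#> 3 synth0003     ok     SL1c    110 -1.124      unfolded              100
#> 4 synth0004     ok     SL1c    110 -1.143      unfolded              100
#> 5 synth0005 no ORF     <NA>     NA     NA          <NA>               NA
#> 6 synth0006 no ORF     <NA>     NA     NA          <NA>               NA
#>   k11_lysine_runs        label
#> 1               2   group3_lea
#> 2               0 not_lea_like
#> 3               2   group3_lea
#> 4               2   group3_lea
#> 5              NA         <NA>
#> 6              NA         <NA>
```

Records 1, 3 and 4 are LEA-like simulants: strongly negative GRAVY
(extremely hydrophilic), unfolded on the charge–hydropathy plane, 100%
windowed disorder and two interlaced period-11 lysine runs — all four
Group 3 LEA hallmarks, hence `group3_lea`. Record 2 encodes a
hydrophobic globular control (`not_lea_like`); records 5–6 are no-ORF
decoys and are reported, not dropped.

The periodicity detector on the worked peptide:

```r
find_periodic_runs("GAGPG", period = 2, residue = "G")
#>   residue period start length positions
#> 1       G      2     1      3   1, 3, 5
```

and a variant leader assigned to its family:

```r
cat <- load_default_catalogue()
classify_family(cat$sequence[cat$name == "Variant5"])
#> $variant  "GGTTTACACCCAGTATCACAAG"
#> $score_sl1 7 ; $score_sl2 14 ; $family "SL2"
```

A command-line wrapper is installed at `inst/cli/leascan.R`
(subcommands `profile`, `sl-scan`, `simulate`); data go to stdout or
`--output`, logs to stderr.

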