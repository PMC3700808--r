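# spliceshield

Does alternative splicing (AS) avoid cutting away pieces of protein–protein
binding sites? When a gene produces an isoform that lacks part of the
canonical protein, the removed stretch may or may not overlap a
protein–protein interface known from a crystal structure. `spliceshield`
implements a statistical pipeline that answers this question for a set of
proteins with structurally characterized interfaces: it extracts interface
residues from structures, encodes each splice isoform as a two-bit string
over the canonical protein, generates randomized-splicing decoy isoforms as
a null model, and compares real versus randomized interface removal with a
stratified Cochran–Mantel–Haenszel (CMH) chi-square test.

The package is aimed at structural bioinformaticians studying the interplay
of splicing and protein interactions, and at anyone needing the underlying
primitives: van-der-Waals contact detection, CDS-coordinate isoform masks,
Poisson-pulsed interval null models, interface redundancy reduction, and
stratified 2×2 testing.

## The model in brief

* **Interfaces.** Two residues on different chains are in contact when some
  atom pair lies within `r_vdw(a) + r_vdw(b) + 0.5 Å`. A *semi-interface* is
  the set of interface residues contributed by one chain, mapped to
  canonical (UniProt-style) numbering through a SIFTS-style table.
  Interfaces are kept only when both sides have ≥ 5 residues and both chains
  cover ≥ 30 % of their protein.
* **Isoform masks.** Each alternative transcript is aligned to the reference
  transcript through the genomic coordinates of its coding exons; residue
  *i* of the canonical protein gets bit 1 ("missing") if any base of its
  codon is absent. Maximal runs of 1s are *missing stretches*; the span from
  the first to the last missing stretch is the *variable region*.
* **Decoys.** For the single-isoform null, each missing and non-missing
  stretch size is redrawn from `Poisson(λ = real size)`, the stretch order
  is kept, and the pulsed variable region is placed uniformly on the
  protein. For the all-isoforms null, isoforms are partitioned into *overlap
  groups* (connected by missing-stretch overlap), each group's segment
  structure is pulsed jointly, and a control is accepted only if pulsed
  missing segments of different groups stay disjoint and retain ≥ 90 % of
  the real missing size.
* **Test.** For each (semi-)interface/isoform pair, a 2×2 table
  (real/decoy × removed/not removed at a removal threshold *t*) forms one
  CMH stratum, so decoys are only ever compared with the isoform they
  derive from. The statistic is
  `(|Σa − ΣE[a]| − c)² / ΣVar[a]` with `E[a] = (a+b)(a+c)/n`,
  `Var[a] = (a+b)(c+d)(a+c)(b+d)/(n²(n−1))`, referred to χ²(df = 1).

## Worked example

Simulate a small study in which splicing is biased *away* from interfaces
(`bias = 0.2`: interface-overlapping exons are skipped five times less
often), then run the full analysis:

```r
library(spliceshield)
library(dplyr)

dir <- tempfile("splice_demo")
simulate_dataset(sim_config(n_genes = 12, bias = 0.2, seed = 42), dir)
run <- run_full_analysis(dir, thresholds = seq(10, 50, 10),
                         n_controls = 200, seed = 42)
run
#> <spliceshield_run>
#>   interfaces kept: 24
#>   isoform masks: 37
#>   result rows: 10
#>   seed: 42  config hash: 0b5e3ed0134c376f26696388b0cb6183

run$results |>
  filter(kind == "hetero", mode == "single") |>
  select(threshold, n_strata, real_frequency, control_frequency,
         statistic, p_value)
#>   threshold n_strata real_frequency control_frequency statistic  p_value
#> 1        10       36         0.1351             0.474     19.11 1.24e-05
#> 2        20       37         0.1351             0.420     13.73 2.12e-04
#> 3        30       37         0.1351             0.345      8.08 4.49e-03
#> 4        40       37         0.1081             0.270      5.41 2.01e-02
#> 5        50       34         0.0541             0.215      6.37 1.16e-02
```

Reading the table: at a 30 % removal threshold, 13.5 % of the real
semi-interface/isoform pairs lose the interface, versus 34.5 % of their
randomized decoys — real splicing removes the binding site far less often
than the randomized null, and the CMH test calls the difference significant
(p ≈ 0.004). `ggplot2::autoplot(run$results)` draws the red/blue
real-versus-randomized frequency curves across thresholds.

The CMH core is exposed directly; a single stratum in which the real
isoform removes the interface while 225 of 1000 decoys do gives:

```r
cmh_test(tibble::tibble(a = 1, b = 0, c = 225, d = 775), correction = FALSE)
#> Cochran-Mantel-Haenszel chi-square test
#>   statistic = 3.429 (df = 1), p = 0.06405
#>   real frequency = 1, control frequency = 0.225
#>   strata: 1 informative, 0 skipped
```

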