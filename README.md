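# mirtail

Quantifying non-templated 3′ nucleotide addition ("tailing") of mature
microRNAs from small-RNA sequencing data.

## The problem

Mature miRNAs are post-transcriptionally modified at their 3′ ends by
untemplated mono- and oligo-nucleotide additions. The terminal uridylyl
transferases Zcchc6 (TUT7) and Zcchc11 (TUT4) selectively mono-uridylate a
small subset of miRNAs carrying a **bipartite sequence motif — GUAG followed
downstream by UUGU** (strict variant UUUGU) — a set dominated by the let-7,
miR-10, miR-99/100 and miR-196 families. When these TUTases are depleted,
uridylation falls and is compensated by a rise in untemplated
3′ adenylation, while overall miRNA abundance stays constant.

Analysing this from sequencing reads is subtle because a terminal U (or A)
on a read is only evidence of enzymatic tailing when the genomic base just
downstream of the miRNA's canonical 3′ end is *different*: a downstream
genomic thymidine (the miR-10a situation) makes a terminal U
indistinguishable from Dicer cleavage heterogeneity. `mirtail` makes this
**templating ambiguity** a first-class concept.

## What the package does

For a read *r* matched 5′-anchored to a mature miRNA *m* of canonical
length *L*, the matched length ℓ is the longest prefix of *r* consistent
with *m* (0 internal mismatches by default, last matched base exact,
ℓ ≥ L − 2), and the tail *t* = r[ℓ..] (≤ 3 nt). With downstream context
*c*, the untemplated portion of *t* is the suffix after the longest prefix
of *t* equal to *c*, and each read is classified as

* **WT** — no untemplated bases (includes templated extensions),
* **U** / **A** — untemplated portion all U / all A,
* **other** — mixed or C/G untemplated bases,
* **ambiguous** — non-empty all-U or all-A tail that is fully templated.

Per-(miRNA, sample) compositions (counts, fractions, RPM) feed the
downstream statistics: the 10 RPM / 1% uridylation filters restricted to
5p-arm miRNAs, rank orders and condition comparisons (ΔU, ΔA, fold
changes), a two-sided Fisher's exact test (minimum-likelihood rule) for
motif enrichment and U→A compensation, and log-scale R² of per-miRNA
abundance between conditions. A seeded simulator generates two-condition
libraries with per-read ground truth so that the whole pipeline is
testable offline.

## Worked example

```r
library(mirtail)

cfg  <- simulation_config(n_mirnas = 12, depth_per_sample = 50000, seed = 7)
pair <- make_depletion_pair(cfg)          # control vs TUTase-depleted
calls <- call_tails(pair$reads, pair$refs)
ct   <- aggregate_composition(calls, reference_sample = "control",
                              refs = pair$refs)
top  <- filter_uridylated(ct, filter_config(reference_sample = "control"))
cmp  <- compare_conditions(ct, "control", "depleted", top)
head(cmp[, c("mirna", "fraction_U_ref", "fraction_U_test",
             "fraction_A_ref", "fraction_A_test", "fold_change_U")], 4)
#>            mirna fraction_U_ref fraction_U_test fraction_A_ref fraction_A_test fold_change_U
#> 1 syn-mir-008-5p         0.0962          0.0139         0.0986           0.162          6.95
#> 2 syn-mir-001-5p         0.0918          0.0000         0.1122           0.133           Inf
#> 3 syn-mir-002-5p         0.0838          0.0108         0.1018           0.167          7.80
#> 4 syn-mir-006-5p         0.0820          0.0198         0.1110           0.173          4.14

compensation_test(ct, top[1], "control", "depleted")
#> $table           U  A
#> control         41 42
#> depleted         6 70
#> p = 3.95e-09, direction: "compensatory"

abundance_concordance(ct, "control", "depleted")
#> [1] 0.9973
```

Eight of the twelve simulated miRNAs pass the 10 RPM / 1% uridylation
filters in the control sample; in every one the U fraction collapses after
depletion (fold changes ≈ 4–8, infinite where the test fraction is 0)
while the A fraction rises — the compensatory adenylation signature — and
per-miRNA total abundance stays concordant (R² > 0.99).

Motif scanning works on any sequence or reference set:

```r
scan_sequence("UGAGGUAGUAGUUUGUACAGUU")   # let-7g: matched, strict UUUGU
#> $matched TRUE  $e1_positions 4 7  $e2_position 12  $strict TRUE
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","mirtail.R",package="mirtail"))') \
    run --mature mature.fa --hairpin hairpin.fa \
    --reads control.fastq,depleted.fastq --samples control,depleted \
    --reference control -o outdir
```

Subcommands: `simulate`, `scan-motif`, `call-tails`, `run`. Outputs are
TSV tables (`motif.tsv`, `calls.tsv`, `composition.tsv`, `comparison.tsv`,
`stats.tsv`) plus a `report.txt` with per-stage read accounting;
identical inputs give bit-identical outputs.

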