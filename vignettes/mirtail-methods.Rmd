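---
title: "mirtail: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtail: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtail)
```

# Scope and model

`mirtail` quantifies non-templated 3′ nucleotide addition on mature
miRNAs from small-RNA sequencing reads and predicts which miRNAs are
substrates of the TUTases Zcchc6/Zcchc11 from sequence alone. Three models
interlock:

1. **a bipartite motif model** for substrate prediction,
2. **a deterministic 5′-anchored matching and templating model** for
   per-read 3′-end classification, and
3. **conditional composition statistics** for comparing a control and a
   TUTase-depleted condition.

All coordinates are 0-based and half-open; all internal sequences are RNA
(T→U on input). These two conventions remove every off-by-one ambiguity
from tail arithmetic and let genomic (DNA) and oligo (RNA) inputs mix.

## The bipartite motif

A sequence is motif-positive when some occurrence of element 2 (`UUGU`)
starts at or after *end of element 1 (`GUAG`) + min_gap* (default 0), with
the gap unbounded above. Both requirements are deliberate: the defining
wild-type substrates span gaps from 1 nt (let-7g) to ~9 nt (miR-10a), so
any upper bound would be an invention. Element-1 self-overlaps are allowed
and all reported, since let-7-family members characteristically carry two
overlapping GUAG boxes. Whether element 2 may overlap element 1 is
genuinely open; we take the stricter reading (no overlap), which all
known positives satisfy. The strict variant substitutes `UUUGU` and marks
the two family members (let-7g, let-7i) that carry the full-stringency
signal. A `one_mismatch_element2` flag (default **off**) exists because a
single U→C change at the last UUGU position hides otherwise-conforming
family members (let-7d, miR-99b); it is off by default because the
reduced stringency measurably costs specificity on random sequence.

Matching is binary — no motif score is computed — because the downstream
use is set intersection and enrichment testing, not ranking.

## Read matching

Published analyses of this kind used a heuristic genome aligner with a
2-mismatch allowance and then re-interpreted 3′ mismatches. We replace
that with a deterministic rule, because the references are short known
sequences and the 3′ end *is* the analyte:

* a read is anchored at the mature 5′ end; `matched_len` is the longest
  read prefix consistent with the mature body allowing `max_internal_mm`
  internal mismatches (default 0, configurable up to the historical 2)
  with the **last matched base exact**, so a 3′ mismatch can never be
  absorbed into the body;
* admissible calls need `matched_len ≥ canonical − 2` (the Dicer 3′
  heterogeneity window; trimmed species beyond −2 are out of scope) and a
  tail of ≤ `max_tail` bases (default 3: the biology is mono- and
  two-nucleotide extension; longer divergence is left unassigned);
* the best candidate maximises matched bases, then minimises mismatches;
  residual ties are multi-mappers and are discarded (conservative, and
  logged) rather than fractionally assigned.

This removes aligner-version nondeterminism: the same FASTQ always gives
byte-identical calls.

## Templating and the ambiguity policy

The downstream context of a mature miRNA is the hairpin (or explicitly
supplied genomic) sequence immediately 3′ of its canonical end, default
depth 3 (tails are capped at 3). For a read matched at a shifted 3′
position the context is re-assembled as *unmatched mature suffix +
downstream context*, so templating is always checked at the actual
matched end. The untemplated portion of a tail is everything after its
longest context-equal prefix. A non-empty, fully templated, homogeneous
U (or A) tail is exactly the undecidable case — Dicer heterogeneity vs
enzymatic addition — and is governed by the ambiguity policy:

* `flag` (default): report as category `ambiguous`, keep in denominators,
  exclude from uridylation rankings (this mirrors how miR-10a, uridylated
  in vitro but trailed by a genomic T, cannot be ranked from reads);
* `drop`: identical per-read computation, but ambiguous reads leave the
  composition denominators;
* `count_untemplated`: ignore templating and classify the whole tail
  (useful as an upper bound on modification rates).

Switching between `flag` and `drop` never changes any read's
untemplated-portion computation — only denominators — and this is tested.

Entries without any context source are classified with an empty context
(every tail base untemplated-callable) and marked `context_free` so
downstream consumers can treat those calls with suspicion.

## Composition, normalization and filters

RPM for a miRNA in a sample is its included read count over all included
assigned reads × 10⁶. Assigned-read normalization (rather than
all-genome-mapped) is the reproducible choice when no genome alignment
exists; per-sample RPM sums to 10⁶ by construction. The read-level
expression filter (default 1 RPM) is evaluated **in the designated
reference sample only** and the surviving sequence set is applied to all
samples, so a condition cannot rescue (or lose) a sequence by changing
its own depth. Consequence worth knowing: a sequence absent from the
reference sample is excluded everywhere.

The uridylated-miRNA filter requires, in the reference sample, category-U
reads at ≥ 10 RPM **and** ≥ 1% of the miRNA's reads, restricted by
default to 5p-arm miRNAs — only 5p species allow unambiguous post-Dicer
interpretation, since 3p 3′ ends can inherit precursor-level uridylation.
Arm assignment uses the name suffix when present (miRBase practice),
otherwise the positional rule *5′ end in the first half of the hairpin ⇒
5p* (midpoint `floor(len/2)`); the positional rule is our choice where no
published definition exists, and suffix/position disagreements are logged
rather than silently resolved.

## Statistics

`fisher_exact` implements the conventional minimum-likelihood two-sided
rule — sum of all hypergeometric tables with the observed margins whose
point probability is ≤ the observed one, with the standard `1 + 1e-7`
relative tie tolerance. The test is named but its sidedness convention is
not published for the quantities we reproduce, so the conventional rule
was chosen and is verified two ways: full enumeration over every 2×2
table with margins ≤ 30, and spot-checks against `stats::fisher.test`.
Degenerate margins return p = 1 with a warning rather than erroring,
so that screens over many miRNAs do not abort. No multiple-testing
correction is applied anywhere, matching the single-test usage being
reproduced. The enrichment universe defaults to all expressed 5p-miRs
(an open choice; the published universe is unstated and it is exposed as
an argument). Abundance concordance is squared Pearson correlation of
log10(RPM + 1): the comparison it reproduces is drawn on log-scaled
axes, and the pseudocount handles zeros.

# The simulator: a stated world

`simulation_config()` fixes the world the tests live in. Defaults and
why:

| parameter | default | rationale |
|---|---|---|
| `n_mirnas` | 20 | desk-scale; enough for rank/filter behaviour |
| `depth_per_sample` | 1e5 | binomial SEs small enough to see 1% categories |
| `mixture` | 0.80 / 0.08 / 0.11 / 0.01 | the composition of a heavily tailed miRNA in control cells (WT/U/A/other) |
| `p_len_minus1` | 0.2 | the −1 nt Dicer isoform is a significant minority of the dominant 22-nt form |
| `p_downstream_U` | 0.25 | downstream genomic U is common among let-7-family loci; exercises ambiguity |
| `oligo_tail_prob` | 0.1 | mono-additions dominate; di-additions exist |
| abundances | log-uniform over 3 decades | reproduces the dynamic range of per-miRNA RPM scatter without fitting real data |
| depletion | `u_reduction = 0.75`, `a_gain = 1.0` | the stated U 8%→2% with A 11%→17% shift |

Ground-truth consistency is enforced *by construction*, per these
generator rules: untemplated tails attach only to canonical-length
bodies (the −1 isoform is emitted for WT reads only); the mature's last
base is fixed to C/G so a −1 body plus tail can never be absorbed into
the body; downstream contexts are a 2-nt U run (with `p_downstream_U`) or
a single C/G — never A — and `other` tails avoid the context base. Every
read therefore carries a well-defined *intended* category and an
*observable* category (what an ideal observer could call given
templating); they differ only where a downstream U makes a U tail
ambiguous, which is the point of `p_downstream_U`.

What the simulator does **not** emulate: ligation and PCR bias, adapter
dimers, sequencing errors by default (`error_rate` exists as a stress
knob but ground-truth labels do not account for substitutions), 3p-arm
reads, 5′ isomiRs, internal editing, oligo-tails longer than 2 nt, and
tailed length isoforms. A green test against this world therefore
establishes correctness of the matching/templating/statistics machinery
— not robustness to library-preparation artefacts.

Two regimes for acceptance testing are deliberately separated:
parameter-recovery runs use `p_downstream_U = 0`, because with a genomic
downstream U the U category is unrecoverable by any method (that is the
biology, not a bug), and that regime is tested on its own: with
`p_downstream_U = 1`, zero category-U calls may be produced under the
default policy.

# Numerical and degenerate-input choices

* Fisher tie comparison uses relative tolerance `1 + 1e-7` (same as the
  reference implementations); the enumeration oracle applies the same
  rule, and agreement is ~1e-15.
* Rank ties are broken lexicographically by miRNA name, making every
  ranking a deterministic permutation.
* `fold_change_U` with a zero test fraction is `Inf` with an explicit
  flag (0/0 → 1); degenerate Fisher margins and all-zero compensation
  tables give p = 1 with warnings.
* Empty read sets, empty composition tables and absent survivors are
  values, not errors; empty reference sets and unresolvable samples are
  hard errors.
* Multi-hairpin mature locations leave `arm = unknown` with a warning;
  duplicated names are hard errors.
* All RNG flows through explicit seeds; per-sample streams derive from
  the master seed and the sample label, and every simulator output is a
  pure function of its configuration.

# Known limitations

* Equivalence with historical heuristic-aligner pipelines is not
  guaranteed — only the stated 3′-mismatch semantics; internal mismatch
  tolerance defaults to 0 (stricter than the historical 2).
* The arm midpoint rule can misclassify unusual hairpins; name suffixes
  take precedence where present.
* The 1 RPM read-level filter excludes sequences unseen in the reference
  sample even if abundant elsewhere; this is faithful to the convention
  being reproduced but can bias gained-modification estimates at low
  depth.
* Cross-species motif intersection counts depend on the reference
  (miRBase) version supplied by the user; no version is bundled.
* `context_free` entries cannot distinguish templated from untemplated
  tails; their calls are upper bounds.
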