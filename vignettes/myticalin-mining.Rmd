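---
title: "Mining linear cationic AMP precursors: models and design choices"
author: "lcamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining linear cationic AMP precursors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcamp)
```

## The biological model

Myticalins are linear, cationic antimicrobial peptides (AMPs) of marine
mussels. Like most secreted AMPs they are translated as prepropeptides with
a stereotyped architecture:

```
signal peptide | mature cationic core | Lys-Arg dibasic site | anionic tail
```

The signal peptide routes the precursor into the secretory pathway and is
removed by signal peptidase. A proprotein convertase then cleaves
immediately after the dibasic pair, releasing the mature core still
carrying the two basic residues. Carboxypeptidase E (CPE) trims C-terminal
Lys/Arg iteratively, and when the exposed C-terminal residue is a glycine,
peptidylglycine alpha-amidating monooxygenase (PAM) removes it and leaves
the preceding residue alpha-amidated. Amidation eliminates the terminal
carboxylate, raising net charge, and — because CPE is a carboxypeptidase
that requires a free carboxylate — it also terminates processing. The
mature peptides are short (23–42 residues), proline/arginine-rich, and have
isoelectric points above 11; the propeptide tail is the mirror image, an
Asp/Glu-rich anionic extension of roughly 35–75 residues.

`lcamp` turns this architecture into an executable discovery pipeline over
assembled transcriptome contigs, plus the physicochemistry, classification,
consensus and pseudogene utilities that surround it.

## The discovery chain

`screen_transcriptome()` applies five gates in order; every open reading
frame (ORF) that enters the chain is logged with the stage that rejected it
(`glance()` on the result tabulates the funnel):

1. **ORF length gate.** All six frames of each contig are scanned
   (`extract_orfs()`). An ORF starts at an `ATG` and ends at the first
   in-frame stop; nested downstream starts are not reported separately
   (longest-per-stop). The gate keeps ORFs *strictly* longer than 50 and
   strictly shorter than 120 codons — the size band of secreted AMP
   precursors — counting codons as amino acids, excluding the stop. ORFs
   that run off the contig end are kept by default because assembled
   contigs are frequently 3'-incomplete; `require_stop = TRUE` drops them.
2. **Signal-peptide gate.** `predict_signal_peptide()` is a transparent
   heuristic with the two classical determinants of cleaved signal
   sequences: a hydrophobic core (an 8-residue window starting at 0-based
   positions 2–20 with mean Kyte–Doolittle hydropathy at least 1.5) and a
   von Heijne (−3, −1) site (smallest candidate signal length 15–30 whose
   −1 residue is in `{A, G, S}` and whose −3 residue is in
   `{A, G, S, T, V, C, I, L}`). We restrict the −1 set to the three
   smallest residues: that choice reproduces the expected cleavage point of
   the family's consensus signal peptide (position 23 of
   `MKGXXLLLLTIXXALCMIXECEG`-like sequences), whereas admitting cysteine at
   −1 would cut inside the hydrophobic core. Users with access to a
   dedicated predictor can inject its cleavage positions through an
   override table (`read_signal_overrides()`); overrides always win.
3. **Cationicity window filter.** A sliding window of 15 residues is scanned
   over the region *after* the predicted signal cleavage — signal peptides
   are hydrophobic, not cationic, so including them would only dilute the
   signal (`window_region = "full"` restores whole-precursor scanning). A
   candidate passes when some window exceeds 30% combined Arg+Pro content
   or has a side-chain isoelectric point above 8. The Arg/Pro test uses the
   combined residue class by default because that is the natural reading of
   an "arginine or proline" content filter; `filter_mode = "either_R_or_P"`
   requires one residue alone to exceed the threshold. Window pI is
   computed from side chains only, since a window is an internal fragment
   with no free termini.
4. **Architecture gate.** `annotate_precursor()` scans for dibasic pairs
   (`KR`, `RR`, `RK`, `KK` — the Lys-Arg site dominates in practice but is
   not universal) downstream of the signal, and accepts the first site that
   leaves a mature core of at least 10 residues and a tail of at least 5
   residues whose side-chain net charge at pH 7 is negative. Anionicity is
   defined by net charge rather than a D+E fraction cutoff (which is still
   reported for diagnostics) because charge is the property the
   architecture actually relies on, and no defensible fraction threshold
   presents itself.
5. **Maturation and reporting.** `mature_from_annotation()` applies the
   convertase/CPE/PAM model; the candidate is profiled
   (`characterize_peptides()`), classified (`classify_subfamily()`), and
   flagged for pI > 11, Arg > 10% and length within 23–42.

## Physicochemistry

Net charge is the Henderson–Hasselbalch sum over ionizable groups,

$$Z(\mathrm{pH}) = \sum_{b \in \mathrm{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_b}}
                 - \sum_{a \in \mathrm{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}},$$

with basic groups N-terminus, Lys, Arg, His and acidic groups C-terminus,
Asp, Glu, Cys, Tyr. An amidated peptide has no C-terminal carboxylate, so
the amidation flag removes that group; this is why amidation can only raise
a peptide's pI. The default pKa set is the Bjellqvist-style table used by
the ExPASy Compute pI tool (`pka_table("bjellqvist")`); an EMBOSS table is
included, and the conclusions the package tests (pI > 11 for the packaged
mature peptides) hold under both. Tables are swappable objects and can be
read from JSON.

The isoelectric point is found by bisection on $Z$ over pH 0–14. $Z$ is
strictly decreasing in pH, so the root is unique; the bracket is narrowed
to $10^{-6}$ pH units (far inside the 0.001 resolution the value is
reported at), which keeps $|Z|$ at the returned pH below $10^{-3}$ even for
long peptides. Degenerate cases return sentinels rather than failing: a
peptide with no acidic group is positive at every pH and reports 14 with
status `always_positive`; no basic group reports 0 (`always_negative`); in
window scans a fragment with no ionizable side chain at all scores a
neutral 7 so that it can never pass the pI > 8 filter.

Percentages in reports are truncated (floored), not rounded: a 10/35
proline fraction reports as 28%, matching the field's convention of quoting
integer percent content.

## Subfamily classification

`classify_subfamily()` evaluates compositional rules in the order A, B, D,
C with the first match winning:

| label | rule |
|---|---|
| A | Arg, Pro, Tyr each > 10% |
| B | Arg, Pro, Thr each > 10%, Tyr ≤ 10%, Trp ≤ 5% |
| D | Arg, Pro > 10% and (Trp > 5% or Thr > 10%) |
| C | Arg > 10%, Pro ≤ 5% |

The B and D descriptions overlap in prose ("Pro, Arg and Thr" vs "Pro, Arg
and Trp or Thr"); the explicit Tyr/Trp guards and the B-before-D order keep
them disjoint, and the packaged worked examples are invariant to this
choice. "Nearly devoid of proline" is quantified as ≤ 5% (the canonical
group-C peptide has none). The rule table is a plain data structure,
serializable to JSON, so users can re-specify it; every call returns the
full evaluation trace so a label can be re-derived from its record.
Classification depends only on composition — permuting residues never
changes a label — which is both its strength (robust, interpretable) and
its limit (it cannot see repeat architecture such as PRY motifs).

## The synthetic benchmark

`simulate_transcriptome()` provides ground truth that real transcriptomes
cannot: it plants precursors whose exact mature products are known, among
decoys engineered to fail exactly one gate each.

A planted precursor is built as: the family-consensus signal template with
its variable positions drawn from `{A, L, S, V}` and up to two further
substitutions (accepted only if they leave the hydrophobic core and the
(−3, −1) site intact); a mature core of 23–42 residues whose composition
guarantees its subfamily rule (e.g. group-A cores carry at least 15% each
of Arg, Pro, Tyr); with probability 0.7 a glycine amide donor before the
`KR` site (the amidated branch); and an anionic tail with ~30% Asp/Glu.
Tail lengths are drawn from 35–75 residues, capped per precursor so the
whole product stays strictly under the 120-codon ORF gate — with a
42-residue core the geometry simply cannot accommodate a 75-residue tail
inside a precursor-sized ORF, so the upper tail range is only reachable for
shorter cores. Cores are arranged with no two adjacent basic residues
(which would create a spurious internal convertase site) and a final
residue outside `{K, R, G}` (so CPE/PAM reproduce the planted product
exactly). Precursors are reverse-translated with uniform synonymous codon
choice (the pipeline is codon-usage-agnostic), wrapped in random UTRs with
an in-frame stop placed immediately upstream of the start codon (so no
upstream `ATG` can absorb the planted ORF), and strand-flipped with
probability 0.5 to exercise reverse-strand extraction.

Decoy classes: `no_signal` (hydrophilic N-terminus, no hydrophobic core),
`low_cationicity` (signal present but the downstream region is acidic and
Pro-free), `no_dibasic` (cationic core, no basic pair anywhere after the
signal), `cationic_but_basic_tail` (complete architecture but a Lys-rich,
positively charged tail). On the default benchmark (50 plants, 500 decoys)
the pipeline recovers every planted mature sequence byte-identically and
every decoy fails at its named gate.

What the benchmark does *not* show: plants are drawn from the generator's
own architecture, so perfect sensitivity demonstrates internal consistency,
not sensitivity on real transcriptomes with divergent signal peptides,
non-canonical cleavage sites, sequencing error or fragmented ORFs. A few
alternate-frame ORFs of decoy transcripts (~1% of decoys) genuinely satisfy
all four gates — a composition filter cannot exclude frame-shifted
cationic sequences — mirroring the manual curation step any real screen
ends with. The generator also models no RNA-seq coverage, polymorphism or
assembly artifacts.

## Numerical and interface conventions

* Coordinates are 0-based half-open on the forward strand of the
  transcript (ORFs) or precursor (regions); when an ORF has a terminal
  stop, its `end` includes the stop codon, and `codon_length` never counts
  the stop.
* `N`-containing codons translate to `X` unconditionally (never "solved"
  even when unambiguous); `X` counts toward length but toward no residue's
  composition fraction.
* Consensus building: per column the most frequent symbol wins, ties broken
  alphabetically with the gap character first; a gap winning at ≥ 50%
  support drops the column (yielding an ungapped consensus, as appropriate
  for a signal-peptide alignment), and any winner below 50% masks to `X`.
* Maturation events are traced in order (`convertase_cut`, `cpe_removed:*`,
  `pam_amidation`); PAM removes exactly one glycine even after a `...GG`
  run, and an amidated product is a fixed point of the processing function.
  A corollary worth noting: a free-acid product never ends in Lys/Arg/Gly,
  but an amidated product may legitimately end in a basic residue when the
  amide donor glycine followed one (amidated-Arg termini exist among
  natural AMPs).
* The mine/characterize/classify/consensus/pseudogene/simulate subcommands
  of the `inst/cli/lcamp` script are thin wrappers over the exported
  functions; `mine` writes a JSON run summary echoing the configuration,
  the per-stage funnel, the seed and an input hash, which is sufficient to
  reproduce a run.

## Problem sizes used in the test suite

The suite validates ORF extraction against a brute-force six-frame
enumerator on 200 random transcripts of 120–450 nt, pI bisection against a
0.0005-step pH grid on 100 random 20-mers, and the full pipeline on the
50-plant/500-decoy benchmark — sizes chosen so the whole suite runs in
about a minute while still exercising every code path; all are seeded and
deterministic.

## Known limitations

* The signal-peptide heuristic is a deliberately simple stand-in for
  dedicated predictors; its false-negative rate on real, divergent signal
  sequences is unknown, which is exactly why external predictions can be
  injected as overrides.
* The dibasic-site model assumes the mature peptide ends at a basic pair
  followed by an anionic tail. The canonical group-C mature peptide as
  printed ends in acidic residues, suggesting the family's C-group boundary
  may not follow the dibasic model exactly; characterization and
  classification therefore operate on printed sequences verbatim, and the
  pipeline may legitimately produce a shorter core for such precursors.
* Coding-potential scoring, homology search, phylogenetics and expression
  quantification are out of scope; the pipeline is a composition-and-
  architecture filter, and its output is a candidate list, not a validated
  AMP inventory.
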