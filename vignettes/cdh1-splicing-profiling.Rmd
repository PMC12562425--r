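---
title: "Junction-level splicing profiling: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-level splicing profiling: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprof)
```

## The problem

Diagnostic laboratories increasingly interpret splicing variants at the RNA
level: a capture RNA-seq run yields, per sample, a table of splice
junctions — pairs of genomic positions bridged by spliced reads, with a read
count and the maximal aligned overhang on each side. Interpreting a
candidate variant then requires two things that are usually missing: a
quantitative *baseline* of the gene's physiological alternative splicing
(which events occur in normal samples, at what level, how often), and a
reproducible way to compare a carrier's junction profile against that
baseline. `spliceprof` implements both for a single reference gene at a
time, with the E-cadherin gene *CDH1* as the packaged worked example:
*CDH1* truncating variants predispose to diffuse gastric and lobular breast
cancer, the gene is on most hereditary-cancer panels, and its splicing
profile in lymphoblastoid cell lines (LCLs) is rich enough to exercise every
part of the machinery — recurrent exon skips, splice-site shifts, a large
partial intron retention and a cluster of alternative first exons inside its
63-kb intron 2.

## The transcript model and coordinates

Everything is referred to one reference transcript
(`transcript_model()`): ordered exons with genomic and cDNA coordinates and
the coding bounds. Coordinates are 1-based inclusive internally; BED input
and output convert from 0-based half-open at the boundary, so HGVS-style
c./r. arithmetic works directly on the internal values. Intronic positions
use signed offsets from the nearer exon boundary (`c.1008+7`,
`c.1566-10`), ties going to the donor side. A junction is stored as the
*spliced-out gap* — first and last intronic base — which makes
canonical-junction comparison an exact tuple match. All cDNA math is
strand-aware; the packaged fixture is on the forward strand, but
reverse-strand models pass the same suite.

The packaged *CDH1* model (`cdh1_model()`) places cDNA position 1 at the
first base of the start codon, so internal cDNA coordinates coincide with
HGVS c. positions. Its c.-space exon boundaries follow the published
*CDH1* splice positions (intron 7 after c.1008, intron 10 acceptor at
c.1566, intron 12 after c.1936, intron 13 after c.2164, and so on). The
genomic coordinates are synthetic — anchored on chromosome 16, preserving
the two features analyses depend on (intron 2 spans 63,258 bp; the exon
4–11 duplication breakpoints 68,841,756 and 68,855,314 fall deep inside
introns 3 and 11) — and the fixture files are named `cdh1_synthetic_*` to
make that explicit.

## Event taxonomy and nomenclature

`classify_junction()` types each observed gap against the canonical
junction set. Endpoint matching is exact (0 bp slack): junction callers
emit exact boundaries, and no fuzz window is defined for this kind of data.
The taxonomy and shorthand:

| kind                      | shorthand | meaning                                      |
|---------------------------|-----------|----------------------------------------------|
| `canonical`               | —         | exact canonical intron                        |
| `exon_skip`               | Δx (Δx_y) | whole exon(s) skipped, canonical flanks       |
| `exonic_donor_shift`      | Δxq       | donor shifted into exon x (terminal loss)     |
| `exonic_acceptor_shift`   | Δxp       | acceptor shifted into exon x (initial loss)   |
| `intronic_donor_shift`    | ▼xp       | donor shifted into intron x (initial retention) |
| `intronic_acceptor_shift` | ▼xq       | acceptor shifted into intron x (terminal retention) |
| `alt_first_exon`          | AFEx+k    | first exon ends k bases into intron x         |
| `unresolved`              | —         | no consistent interpretation                  |

The ▼xq form is a symmetric extension of the published donor-side
convention (only ▼xp is in routine use); it is needed so acceptor-side
intronic shifts can be named generically. Each typed event also carries an
HGVS-style r. string in a deliberately restricted dialect —
`r.<pos>_<pos>del` for exonic loss, `r.<pos>_<pos>ins<pos>_<pos>` with
offset notation for intron retention (`r.2164_2165ins2164+1_2164+1270`).
`parse_r_description()` inverts `format_event()` exactly; this is not a
general HGVS parser and does not try to be. Alternative first exons get no
r. string: the upstream exon structure is unknown by construction, so they
are labelled `AFE<intron>+<offset>`.

### Distinguishing intron retention from alternative first exons

A donor inside intron x splicing to the canonical start of exon x+1 is
observationally ambiguous: it could be partial retention of intron x on the
canonical transcript (▼xp) or the terminal junction of a novel first exon.
Three signals resolve it:

1. **Retained-length plausibility.** The donor offset equals the length of
   the implied retained segment. Reported partial retentions run to about
   1.3 kb; a donor 50 kb into an intron would imply a 50-kb retained mRNA
   segment, which is not credible. Offsets up to `max_shift_offset`
   (default 2000 nt) are typed as ▼xp, deeper donors become
   alternative-first-exon candidates.
2. **Cryptic-exon partner search.** If the sample also contains a
   *non-canonical* junction from the preceding exon's end landing inside
   the intron at or upstream of the donor, the pair indicates a cryptic
   internal exon, and the deep donor is typed as a retention-side event
   instead. The canonical junction itself does not count as a partner —
   the physiological transcript coexists with novel first-exon isoforms,
   so its presence carries no information here.
3. **Depth gate.** Absence of a partner junction is only evidence if the
   sample was deep enough to have seen one. Samples below `afe_min_depth`
   total junction reads (default 1000) leave deep donors `unresolved`.

One tie-break is defined for completeness: a gap compatible with both an
exon-skip and a shift interpretation can only arise on degenerate models
with zero-length introns and resolves to `exon_skip`; it is unreachable on
real models.

## Quantification, filters and confidence

The expression ratio is **alt-to-physiological**, not alt-to-total:

$$\mathrm{ratio} = 100 \times \frac{\text{reads(alt junction)}}{D},$$

where \(D\) is the mean read count of the physiological counterpart
junction(s) in the same sample — the two canonical junctions replaced by an
exon skip (their mean by default; an upstream-only switch exists for
capture designs with 3'-biased dropout), the host-intron canonical junction
for any splice-site shift, and the same-acceptor canonical junction for an
alternative first exon. The alt-to-physiological choice is forced by the
data this method must represent: observed first-exon junctions reach 134%
of the reference junction, which no proportion-of-total could express. A
zero counterpart makes the ratio undefined (flagged, never infinite).
The ratio is scale-invariant in sequencing depth and monotone in the
alternative read count; both are property-tested.

Two independent annotations are attached per sample:

* **Reporting filters** (`filter_config()`): an event is reported when its
  junction has ≥ 100 reads *and* a ratio above 0.1% (strict `>` per the
  usual wording of the cutoff; configurable to `>=`). Recurrence and
  cohort means are computed over filter-passing samples.
* **Confidence tiers** (`confidence_config()`): `high` needs ≥ 30 bases of
  overhang on both sides and more than 50 reads; `moderate` needs the
  overhang condition and 30–50 reads; everything else is `low`. The
  apparent tension with the 100-read reporting filter is deliberate:
  confidence describes junction *evidence*, filters gate event
  *reporting*, and a low tier never silently drops an event.

## Coding consequence and NMD

`predict_consequence()` classifies frame from the net coding-length change
modulo 3 (deleted exonic span clipped to the CDS; retained intronic length
when the insertion point is inside the CDS). With an explicit coding
sequence the altered frame is scanned for the first stop codon (a plain
three-codon scan; no translation machinery is needed) and NMD candidacy
uses the canonical boundary rule — a premature stop more than
`ptc_rule_nt` (default 50, configurable 50–55) nucleotides upstream of the
last exon–exon junction. Without sequence, the PTC position is omitted and
a frameshift is assumed to terminate shortly after the change start, which
is the standard expectation (an out-of-frame read of coding sequence meets
a stop about every 20 codons). Events confined to non-coding regions never
change frame, and alternative first exons are reported as
"effect on translation start not predicted" rather than guessed.

## Tandem duplications

A tandem direct duplication of exons a..b yields the exon walk
`1..b, a..b, (b+1)..n`. Internal events (whole-exon skips) apply
independently to the proximal and distal copy of their host exon — the
biological motivation being that a duplication with deep intronic
breakpoints preserves the splicing regulation of both copies — giving
\(2^k\) combinations for \(k\) (event, copy) pairs, deduplicated on the
labelled exon sequence (structural identity, not net length: two different
structures of equal length are distinct transcripts). Inverted
duplications raise an explicit unsupported error.

Consequences are assessed per transcript two ways: net length change
modulo 3, and a segment walk flagging any exon occurrence read outside its
native frame. The second test matters: in the packaged *CDH1* exon 4–11
example, skipping *both* exon-11 copies gives a net change of +1032 nt —
a multiple of three — yet the 1032 out-of-frame nucleotides upstream
guarantee an internal stop, so the transcript is still truncating. All
four combinations are truncating and no splicing rescue exists, which is
exactly why enumerating the internal-event combinations is required before
classifying a large rearrangement: a combination that restored both frame
and native phasing would have changed the clinical conclusion.

## Variant assessment

`assess_variant()` compares one carrier against the remaining cohort
within a window around the variant locus (host exon/intron ± 1 exon by
default — the programmatic counterpart of the expert's visual inspection
of the locus). Aberrant events are filter-passing carrier events whose
control prevalence is at most `max_control_prevalence_pct` (default 10%).
Evidence is assigned by one rule: *pathogenic-supporting* requires at
least one aberrant, carrier-specific, truncating event at or above the
dominance threshold (`dominance_pct`, default 50% of the physiological
counterpart). The default separates the regimes seen in practice:
physiological alternative events top out near 40% of their counterpart,
while pathogenic transcripts in carriers sit at 135–250%. No aberrant
event at all yields *no-splicing-effect-detected*; anything in between is
*inconclusive*. The labels are deliberately not ACMG codes — mapping to
ACMG/ClinGen criteria is left to the user, because the rule here encodes
an observation, not a classification policy.

Allelic imbalance is flagged when the host intron's canonical junction
reads are at most `imbalance_frac` (default 0.25) of the carrier's own
flanking canonical junction depth. The flag reports depletion of the
wild-type transcript only; it cannot distinguish somatic allele loss from
promoter methylation or any other mechanism, and does not try. In-silico
scores (SPiP, SpliceAI) are stored verbatim as annotations and never
computed or interpreted.

## The synthetic cohort generator

`generate_cohort()` produces junction tables with the statistical
structure the analysis assumes. Per sample: canonical junction reads are
Poisson(\(D\)); each profile event is present with probability
recurrence/100; present events draw alternative reads as
Binomial(counterpart draw, ratio) for ratios ≤ 100% and Poisson(ratio
× \(D\)) above 100% (a binomial cannot produce the >100% regime the ratio
definition admits); overhangs are uniform on 30–70 bases. NMD-sensitive
events are scaled by `nmd_factor` (default 0.2) when the cohort is
generated without puromycin, emulating decay of unstable transcripts in
untreated cells. Generation is deterministic given the seed, and the
ground-truth table is emitted alongside but never read by the analysis.

The packaged `cdh1_event_profile()` encodes the 11-event LCL profile:
exon-6 skip 4.4% (100% recurrence, NMD-sensitive), exon-11 skip 14.1%
(100%, NMD-sensitive), exon-14 acceptor shift 6.1% (100%), exon-13 donor
shift 1.4% (50%), intron-13 partial retention 0.7% (50%), and six
intron-2 alternative first exons — two known (assigned 10% each: no
published level exists for them, and only their count and known/novel
status matter downstream; the placeholders are marked as such) and four
novel at 26, 35.8, 74.1 and 134% with recurrences 85, 90, 95 and 100%.
The default canonical depth is 50,000 reads per junction, a typical
capture depth at which even the 0.7% event clears the 100-read reporting
filter; parameter-recovery checks run at depth 10,000 with 20 samples,
averaged over a handful of seeds, which bounds the standard error of each
estimated mean well below the 3–5% relative tolerances asserted.

What the simulation does **not** emulate — and what passing tests
therefore do not demonstrate about real data: mapping and capture bias,
overdispersion beyond Poisson/binomial, correlated events on one
transcript, partially degraded RNA (FFPE), index hopping, or any
read-level artefact. The generator validates the *pipeline arithmetic*
(typing, ratios, filters, recurrence, evidence rules) under the stated
sampling model, nothing more. Per-sample spread of the exon-11 skip in
real LCLs (5.8–39.5% around a 14.1% mean) is wider than pure counting
noise; the generator matches the mean exactly and the spread only
loosely.

## Degenerate inputs and numerical choices

Zero-length gaps are validation errors; junctions outside the transcript
span are `unresolved` with a reason, as are single-exon models (which
also warn when canonical junctions are requested). Zero counterpart
depth gives an undefined ratio with a reason. Empty cohorts make
recurrence an error rather than NaN. Duplicate annotation spans merge
their labels with a warning on conflict. All randomness flows from a
single integer seed.

## Known limitations

* Full-length isoforms are out of reach by design: events are documented
  junction-by-junction, so co-occurrence of two events on one molecule is
  unknowable from short-read junction counts.
* Two published event descriptions disagree internally with their own r.
  strings: the exon-14 acceptor shift is described as removing 35 bases
  while `r.2165_2198del` spans 34, and the exon-12 donor shift as
  removing 160 while `r.1831_1936del` spans 106. The fixture records the
  r. strings and the package computes from them; the discrepancies are
  documented here rather than silently reconciled.
* The exact protein-level string for the exon-11 skip
  (p.(Tyr523Phefs*16)) requires the real mRNA sequence, which the package
  does not ship; consequence prediction with an explicit CDS is supported
  and tested on synthetic sequences instead.
* Junction provenance (uniquely-mapping reads or not) differs between
  extractors; the manifest carries a free-text provenance field instead
  of guessing.

## A minimal run

```{r, eval = FALSE}
model <- cdh1_model()
sim <- generate_cohort(cdh1_event_profile(model),
                       sim_config(n_samples = 20, seed = 1), model)
events <- annotate_cohort(sim$cohort, model, cdh1_known_junctions())
quant <- quantify_cohort(events, model)
cohort_profile(quant)
```
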