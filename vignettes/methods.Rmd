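---
title: "Determining gynecologic surgical history from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining gynecologic surgical history from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gynsurgnlp)
```

## The problem

Gynecologic surgeries — hysterectomy, unilateral oophorectomy, bilateral
oophorectomy, and their combinations — often predate a health system's
electronic record by decades, and the evidence for them is scattered through
free-text clinical notes as terse history lines ("s/p TAH-BSO 1995"),
operative report fragments, patient-reported recollections, and copy-pasted
boilerplate. Research on aging outcomes after these surgeries needs a single
patient-level label, assigned as of a follow-up date, from six mutually
exclusive categories:

1. no surgery
2. bilateral oophorectomy only
3. hysterectomy and bilateral oophorectomy
4. unilateral oophorectomy only
5. hysterectomy and unilateral oophorectomy
6. hysterectomy only

`gynsurgnlp` implements a deterministic rule-based pipeline that produces
this label from longitudinal notes, the evaluation machinery to score it
against a gold standard (including chance-corrected agreement and
record-truncation analyses), and a seeded synthetic corpus generator that
emulates the information gaps of single-institution records. Every stage is
rule-based rather than statistical: the intended use is auditable
epidemiological phenotyping, where each extracted event must be traceable to
a sentence and a rule.

## The extraction pipeline

A note passes through five stages, each a pure function of its inputs.

**Section segmentation.** Headers are recognized at line starts (the default
pattern accepts upper-case headed lines such as `PAST SURGICAL HISTORY:`);
text before any header forms a synthetic `UNKNOWN` section. Only sections
relevant to the patient's own history are processed further. The default
whitelist covers present-illness, medical/surgical history, procedures,
gynecologic history, and report/impression sections; family history, social
history, allergies and medication lists are excluded, so a mother's
hysterectomy in a `FAMILY HISTORY` block can never become a patient event.
Whether unsectioned (`UNKNOWN`) text is processed is configurable and
defaults to yes, because a large share of real notes carries no headers at
all; excluding it would silently discard most short history notes.

**Sentence detection and tokenization.** Sentences end at terminal
punctuation followed by whitespace, or at newlines (clinical notes are
strongly line-oriented). A small abbreviation list (`Dr.`, `vs.`, etc.)
and the requirement of trailing whitespace keep decimals, slash dates and
`s/p` intact. Tokens are lowercased; hyphen- and slash-joined compounds
(`tah-bso`, `s/p`, `salpingo-oophorectomy`, `11/22/1994`) stay whole, which
is what makes abbreviation matching and date extraction reliable.
A rule-based splitter was chosen over a statistical one deliberately:
determinism and auditability outweigh the marginal accuracy a learned model
might add on well-formed prose, which clinical notes are not.

**Concept matching.** A YAML lexicon maps four concepts — hysterectomy,
oophorectomy, bilateral oophorectomy, and the combined TAH-BSO form — to
token-level surface patterns. Matching is longest-match-wins, left to
right, without overlaps, so "bilateral salpingo-oophorectomy" is one
bilateral-oophorectomy mention, not a stray oophorectomy. Exclusion tokens
(`hysteroscopy`, `biopsy`, `oophoropexy`, `cystectomy`) veto any match
within a three-token window; these are exactly the confusables that produce
false surgical histories in practice. The bare abbreviation "SO" is *not*
in the default lexicon: after lowercasing it is indistinguishable from the
English word "so", and the false-positive cost would dwarf the handful of
genuine uses; the sided forms LSO/RSO/USO are included. The combined
TAH-BSO concept is kept as a single mention for auditability and expanded
into hysterectomy + bilateral oophorectomy at aggregation.

**Assertion classification.** A NegEx/ConText-style scoped cue search
assigns each mention one of five labels: positive, negated, hypothetical
(discussed/considered), planned, or family-related. Cues are token
sequences scanned in windows of six tokens before and after the mention;
the scan stops at scope breakers (`but`, `however`, `;`, `.`), so "she
denies pain but had a hysterectomy" stays positive. Precedence when several
classes fire is negated > family > hypothetical > planned. A mention inside
a family-history section is forced to family regardless of cues. The window
size and cue lists are configuration, not code; six tokens is the
conventional NegEx default and was fixed before any evaluation. **Only
positive mentions become valid events**; everything else is retained solely
for the audit trail.

**Laterality and dates.** For oophorectomy-family mentions, sentence-scoped
cues resolve the side: explicit bilateral wording wins, then `left`/`right`
(both present resolves to bilateral — the rule for that conflict is a design
choice, documented and configurable in spirit: a sentence naming both sides
almost always describes a staged pair). No cue leaves the side unspecified.
Dates are extracted from three pattern families — full slash dates, slash
dates with two-digit years, and bare years — with two-digit years pivoted
into the century ending at the note date and bare years accepted in
[1900, note year]. Slash dates are read month-first by default (a day-first
dialect is available) because the target corpora are US clinical text and a
month-first reading avoids silently impossible dates. The nearest date in
the same sentence is attached to each mention; ages at surgery ("at age
30") are deliberately *not* converted to dates, reproducing the documented
sparsity of usable surgery dates rather than papering over it. Dates are
never attached across sentences.

## Patient-level aggregation

Valid events from all notes up to the follow-up date are pooled as a set —
duplicates from copy-paste repetition collapse naturally under set
semantics over (concept, laterality). Two rules then decide the label:

* **Left-side default.** An oophorectomy with no laterality cue counts as a
  left-side (unilateral) oophorectomy.
* **Extent resolution.** Any explicitly bilateral event forces bilateral;
  otherwise a documented side set of both left and right — two staged
  unilaterals — is bilateral (the removal of the remaining ovary completes
  a bilateral oophorectomy); one documented side is unilateral.

Crossing hysterectomy presence with extent yields the six statuses. The
default ("faithful") mode unions all valid events, so a single stray
bilateral mention forces a bilateral label even when other notes say
otherwise — this reproduces the documented behaviour of the rule set and
deliberately exposes the correction-over-time failure mode for study. An
optional evidence-weighted mode instead trusts the most authoritative
source type present (operative > pathology > radiology > clinical note)
for conflicting oophorectomy evidence; it is off by default.

Events whose attached surgery date postdates the note date are kept and
logged, not dropped: notes do occasionally reference scheduled corrections,
and the aggregation uses note availability, not event dates, as its filter.

## Evaluation machinery

`evaluate_statuses()` computes one-vs-rest precision, recall and F1 per
class, their macro (unweighted) and support-weighted averages, accuracy,
percent agreement, and Cohen's kappa
(κ = (p~o~ − p~e~)/(1 − p~e~)). Conventions worth stating:

* Zero-denominator precision or recall is reported as 0 with a warning; F1
  is 0 when precision + recall is 0.
* Weighted averages weight by gold-label supports of the evaluation set.
  Weighting by predicted supports or by design counts would be equally
  defensible; the choice is configurable through the `supports` argument of
  `weighted_average()`.
* Metrics are computed in full precision and conventionally rounded to 2
  decimals (percentages to 1) only for display.

`recovery_curve()` quantifies how much of full-record performance survives
record truncation: for window length *k*, only notes within the last *k*
years before each patient's follow-up date are kept, the pipeline is rerun,
and R(k) = F1w(k)/F1w(all) is reported. R is 1 at the full record by
construction and can exceed 1 only if truncation removes misleading text
(logged when observed). Extraction is per-note and deterministic, so events
are extracted once and filtered per window.

`summarize_discrepancies()` tabulates analyst-assigned discrepancy labels
against a fixed three-way taxonomy — external information gaps (the record
never had the history), internal gaps (the record contradicts itself:
corrections over time, confusable terms, typos, flipped sides) and
technical errors of the extraction itself (missed negation, family
history, discussion read as fact). The categorization of individual
patients is analyst work; the package only does the arithmetic.

## The synthetic corpus generator

No real clinical corpus can ship with the package, so `generate_corpus()`
produces dossiers with known ground truth. Its defaults encode the study
conditions the package targets:

* status distribution proportional to the reference cohort composition
  (38.1% no surgery, 43.5% hysterectomy + bilateral oophorectomy, 5.5%
  unilateral only, 6.4% hysterectomy + unilateral, 5.6% hysterectomy only,
  0.9% bilateral only);
* follow-up dates uniform over January 1997 – August 2019;
* surgical patients carry 1, 2 or 3 distinct surgery dates with mixture
  (0.863, 0.127, 0.010), restricted to what the drawn status permits (a
  staged bilateral needs two dates);
* a date is attached to a surgery sentence with probability 0.62,
  otherwise an age phrase or nothing — matching the documented sparsity of
  surgery dates; rendered dates mix the three pattern families.

Timelines are internally consistent by construction (no ovary is removed
twice; bilateral removal terminates the sequence), and a consistency test
feeds every generated timeline back through the status resolver. Each
procedure gets an anchor note shortly after its date; later notes restate
older surgeries with probability 0.25. Each unilateral oophorectomy is
phrased consistently across its mentions — always with its side or always
unsided — as a single documentation trail would be; mixing the two would
manufacture spurious bilateral labels through the left-side default, which
is a property of inconsistent documentation (covered by the laterality-flip
noise), not of faithful documentation.

Noise processes mirror the information-gap taxonomy, each with its own
rate and each logged to a per-patient ledger with its taxonomy subcategory:
external gaps (dropping every note that documents a surgery, emulating
external-institution care at rate 0.05 per surgery; truncating pre-1997
notes at rate 0.02 per patient), internal gaps (copy-paste-propagated false
claims at 0.01 per patient, concept-word typos at 0.01 and laterality flips
at 0.01 per sentence), and extraction stressors (negated mentions at 0.10,
family-history mentions at 0.05, hysteroscopy/biopsy confusables at 0.05,
discussed surgery at 0.05 and planned surgery at 0.02 per note). The
distractor rates are an order of magnitude above what the default external
and internal rates would need to reproduce observed discrepancy shares, on
purpose: they exist to stress the assertion rules, not to calibrate error
rates. Note counts per patient (Poisson, mean 6 background notes over a
25-year window) are order-of-magnitude choices — real note-count and
note-length distributions are not public — and are exposed in the
configuration.

Randomness is fully seeded; per-patient substreams are derived from the
master seed, so patient *i*'s dossier is stable when the corpus size
changes, and identical configurations write byte-identical files.

**What passing tests on this corpus do and do not show.** The generator's
language is templated: roughly forty sentence patterns, uniform section
structure, no misspellings beyond the injected typo process, no OCR noise,
no genuinely ambiguous phrasing ("right salpingo-oophorectomy versus right
lower quadrant"), no coreference, and no age-to-date reasoning. Perfect
recovery on a noiseless synthetic corpus therefore demonstrates that the
pipeline's rules compose correctly — that negation, family context,
laterality, staging and aggregation interact as specified — not that the
lexicon or cue lists are complete for any real institution's notes. The
degradation experiments show the *structural* consequences of information
gaps (accuracy falls monotonically with external-gap severity, errors are
dominated by false negatives), which is the mechanism the package exists to
study; absolute error rates on real text will differ.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, character-based throughout, so every
  span slices its source text exactly.
* An empty note, an empty section list, or an unmatched sentence yields an
  empty, correctly-typed events table, never an error.
* Metrics on an empty confusion matrix, a zero full-record F1 in the
  recovery ratio, and aggregation input containing post-follow-up events
  are errors with classed conditions (`gsn_data_error`,
  `gsn_config_error`), so callers and the CLI can map them to exit codes
  (0 success, 1 usage/configuration, 2 data).
* Cohen's kappa with chance agreement 1 is defined as 1 when observed
  agreement is 1 and an error otherwise.
* The specimen-template line `"Uterus, endometrium, hysterectomy:
  Inactive"` *is* matched by default ("faithful" mode reproduces the
  documented behaviour of the original rule set, including this known
  error); `mode = "strict"` suppresses matches on such colon-terminated
  template lines.
* Two-digit year pivoting uses the century window ending at the note year,
  so `03/05/99` in a 2001 note is 1999, never 2099.

## Validation problem sizes

The shipped test suite exercises the exhaustive aggregation truth table
(all 32 subsets of a five-event pool against an independent ovary-set
oracle), 200 random confusion matrices against brute-force metric oracles
at 10^-12^, negation closure over the full lexicon surface bank, a
corpus-wide left/right swap test, noiseless end-to-end recovery on 500
patients, an external-gap severity sweep (drop rates 0/0.1/0.3/0.5, 20
seeded replicates of 50 patients each), and recovery-curve monotonicity
over 20 seeded replicates of 60 fully-dated patients. These sizes keep the
whole suite within a few minutes while leaving the stochastic checks with
comfortable margins (the degradation sweep pools 1,000 patients per noise
level).

## Known limitations

* The lexicon and cue lists are re-authored defaults, not a validated
  institutional vocabulary; both are YAML and meant to be edited.
* Ages at surgery are not converted to dates; date association is strictly
  within-sentence.
* Coreference ("it was removed in 1998") and cross-note temporal reasoning
  are out of scope.
* The evidence-weighted aggregation mode is a simple source-rank heuristic,
  provided for studying conflict resolution, not a validated adjudicator.
* Scanned/paper records and OCR artifacts are not modelled.
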