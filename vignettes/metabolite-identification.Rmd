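---
title: "Identifying artemisinin metabolites from MSE peak lists: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying artemisinin metabolites from MSE peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artmetab)
```

## The problem

Artemisinin (ART, C15H22O5) is metabolised rapidly in vivo, and its phase-I
metabolites can also be produced at scale by microbial transformation with
*Cunninghamella elegans*. Deciding whether the fungal system is a faithful
surrogate for mammalian metabolism reduces to a data-analysis question: given
data-independent acquisition (MSE) LC-MS runs of mouse plasma and of
fermentation broth, which drug-derived components are present in each system,
what are they, and how large is the overlap?

`artmetab` implements that identification logic as a pipeline over centroided
peak lists:

1. **Blank subtraction** — remove peaks also present in a paired drug-free
   control (same energy channel, within m/z and retention-time tolerances).
2. **Candidate enumeration** — compose biotransformation rules on the parent
   formula to generate the plausible metabolite classes.
3. **Precursor matching** — match surviving low-energy ions to candidate
   `[M+H]+`, `[M+Na]+`, `[M+K]+` m/z within a milli-Dalton window.
4. **Fragment confirmation** — explain co-eluting high-energy fragments as
   neutral-loss paths from the precursor and score coverage.
5. **System comparison** — join identifications across systems and compute
   the in vivo / in vitro / common sets, per-class tallies, and Rt windows.

## Mass arithmetic

All masses are monoisotopic and fixed to IUPAC/CODATA constants embedded in
the package (H 1.007825, C 12 exactly, N 14.003074, O 15.994915,
Na 22.989770, K 38.963707; proton 1.007276, electron 0.000549 Da), so results
are reproducible without an external atomic-mass table. Adduct m/z is the
neutral mass plus the cation mass, with the electron mass subtracted for the
charged species:

```{r}
ion_mz("C15H22O5", "M+H")   # protonated artemisinin
ion_mz("C15H22O4", "M+Na")  # sodiated deoxyartemisinin
```

Subtracting the electron mass matters at this accuracy scale: it shifts
sodiated and potassiated ions by 0.55 mDa, and including it reproduces the
study table's printed errors (e.g. deoxyartemisinin at -0.5 mDa,
dihydroartemisinin at -1.1 mDa) to 0.1 mDa, whereas omitting it degrades the
agreement. Only singly charged positive ions are supported — every ion in
this chemistry is singly charged — and isotope patterns are out of scope.
Mass errors are reported in mDa, `(observed - theoretical) x 1000`, rounded
to one decimal with halves away from zero (`round_mda()`), matching the
sign-preserving one-decimal reporting convention of the source table.

## Candidate enumeration

Three formula-level rules generate every observed class: hydroxylation
(`+O`), loss of a peroxide oxygen (`-O`), and carbonyl/lactone reduction
(`+H2`). Paths are unordered multisets — at the formula level, `+O` then
`-O` equals `-O` then `+O` — and candidates are deduplicated by path, never
by formula, because path identity is what carries the class label.

Caps are configuration, not chemistry: the observed panel contains no
triple-hydroxylation and no double reduction, so the defaults are `+O` at
most twice, `-O` and `+H2` at most once, three steps total. One further
refinement is needed to span exactly the nine observed classes:
dihydroxylation is only observed on the intact parent skeleton, never on a
deoxygenated or reduced one. Each rule therefore carries a second cap,
`max_uses_combined`, applying when the path contains any other rule type
(`+O`: 2 alone, 1 combined). Without it the free closure would also emit
`de-ART + 2O` and `DHA + 2O`, classes with no observational support. Both
caps are user-configurable (`read_rule_set()`).

```{r}
enumerate_candidates("C15H22O5")
```

Note the two isobaric collisions — `de-ART + O` shares C15H22O5 with the
parent, and `DHA-O + O` shares C15H24O5 with DHA. They are deliberate: the
study's panel distinguishes such isomers by retention time and fragments,
not by mass.

## Precursor matching

The precursor tolerance defaults to +/-2 mDa, the accurate-mass window of
the acquisition software used in the source study. Matching is
tolerance-monotone (widening the window only adds matches), and each peak is
reduced to one best match by a deterministic tie-break: smallest absolute
error compared at the 0.1 mDa reporting precision, then fewest
biotransformation steps, then lexicographically smaller class label. Because
of the isobaric collisions above, a genuine `de-ART + O` peak best-matches
`ART` and a genuine `DHA-O + O` peak best-matches `DHA`; every
within-tolerance alternative is therefore retained in a diagnostics column,
and downstream recovery scoring accepts a metabolite as found when its true
class appears among best match or alternatives. Retention time plays no role
in matching itself — mass determines class, Rt separates isomers.

## Fragment annotation

High-energy fragments are explained as multisets of neutral losses from the
precursor, drawn from a registry that defaults to H2O, HCOOH, CH3COOH, CO
and C2H4 (masses derived from the formulas, never typed in), with at most
one +/-H2 hydrogen rearrangement per fragment — single hydrogen-pair
transfers are the only rearrangement this chemistry requires. The search
(`explain_fragment()`) returns a minimal-cardinality solution; a brute-force
enumerator (`explain_fragment_oracle()`) exists purely as a test oracle and
the two are cross-checked on hundreds of random instances.

Numerical choices:

* **Fragment tolerance 0.5 Da** by default, because reference fragment lists
  are printed at nominal mass; tighten to mDa for accurate-mass data.
* **Tie-break among equal-length solutions**: no hydrogen adjustment
  preferred over `+H2` over `-H2`, then registry order. Registry order
  (water first, ethylene last) ranks the chemically common losses first;
  it is what assigns a nominal 28 Da loss to CO rather than C2H4 — the two
  are isobaric at 0.5 Da (27.9949 vs 28.0313) and alphabetical or
  smallest-error tie-breaks would both pick C2H4, contradicting the
  established fragmentation scheme for deoxyartemisinin.
* **Protonated ladder**: fragments are always matched against the `[M+H]+`
  ladder of the candidate formula, even when the precursor was detected as
  `[M+Na]+` or `[M+K]+`; sodium and potassium ions behave as adduct clusters
  and the fragment series continues from the protonated species.
* **Coverage** is explained fragments over considered fragments, with
  consideration capped at the 10 most intense (the acquisition software's
  per-match fragment cap). An empty fragment list yields a not-evaluable
  annotation (`coverage = NA`), deliberately distinct from coverage 0.

With these defaults the full printed fragment list of each reference
compound (artemisinin, deoxyartemisinin, dihydroartemisinin) is covered at
1.0:

```{r}
refs <- read_reference_compounds()
vapply(seq_len(nrow(refs)), function(i)
  annotate_spectrum(refs$formula[i], refs$fragments[[i]])$coverage,
  numeric(1))
```

## The packaged fixture and its validator

`read_metabolite_fixture()` returns a verbatim transcription of the study's
39-metabolite summary table. Verbatim means including its typos: a printed
formula inconsistent with its own observed m/z (M11, M38), an observed m/z
inconsistent at tens of mDa (M21 in vitro, M26 in vitro), and pairs of rows
whose identical observed m/z carry different printed errors (M2/M3).
`validate_fixture()` recomputes every per-system mass error from the printed
formula + adduct and grades the discrepancy — pass (<= 0.05 mDa),
warn (<= 0.3 mDa), fail — reporting rather than repairing, so the audit
trail of the source data stays visible. The dihydroartemisinin `[M+H]+`
reference value is likewise stored as printed although it sits ~25 mDa from
the theoretical protonated C15H24O5; it is excluded from the 2 mDa
reference-ion checks as a flagged inconsistency.

`replay_fixture()` reproduces the headline comparison from the fixture:

```{r}
replay_fixture()$n
class_counts(read_metabolite_fixture(), "common")
rt_range(read_metabolite_fixture(), "ART + O")
```

## Cross-system identity

For fixture records, "same metabolite in both systems" is sharing a table
row. For pipeline output there is no shared row, so records are joined by
(class label, |dRt| <= 0.1 min), nearest retention time first, one-to-one —
retention time is the study's own instrument-level alignment between
systems. This join has a known limitation: two genuinely different isomers
of the same class, observed in different systems at indistinguishable
retention times, are merged. The default synthetic panel (which mirrors the
study's table) contains exactly one such pair — an in-vivo-only and an
in-vitro-only dihydroxylation isomer both at 2.2 min — so the noiseless
pipeline reports a common set of 17 where the truth is 16, while recall and
precision remain 1.0 because every individual metabolite is still recovered.
Fragment-based disambiguation of co-eluting isomers would require spectral
similarity scoring across systems and is out of scope.

## The synthetic generator

`simulate_dataset()` produces ground-truthed paired sample/blank MSE peak
tables so the whole pipeline is testable without deposited raw data (none
exist for this study). What it emulates:

* low-energy precursor ions at theoretical adduct m/z plus Gaussian error,
  sigma defaulting to **0.5 mDa** (typical accurate-mass scatter of a
  well-calibrated Q-TOF, a quarter of the matching window);
* high-energy fragments at sampled neutral-loss masses below the protonated
  ladder, log-uniform intensities, jittered retention times (sd
  **0.02 min**, small against the 0.1 min join window);
* a matrix background shared verbatim between each sample and its blank
  (30 peaks), plus Poisson-count decoys (mean **25** per sample) uniform
  over the 50-1000 scan range but rejection-sampled to lie > 5 mDa from
  every candidate ion, so noise is mass-distinguishable from signal;
* a default truth panel mirroring the study's 39 metabolites (classes,
  adducts, retention times, system membership — hence a 23/32/16 Venn by
  construction).

What it does not emulate: chromatographic peak shapes, isotope envelopes,
ion suppression, in-source fragmentation, or decoys engineered to collide
with candidate masses. Passing the end-to-end tests therefore demonstrates
the correctness of the identification logic under a clean instrument model,
not robustness to pathological real-world interference.

All randomness flows from the single seed in `synthetic_spec()`; identical
specs give identical tables. In the noiseless, decoy-free limit the pipeline
recovers the truth exactly (recall = precision = 1.0), and under the default
0.5 mDa noise, recall at the 2 mDa window stays at 1.0 over repeated seeds
while an artificially narrow 0.1 mDa window loses most metabolites —
the tolerance-monotonicity the matching stage guarantees. The test suite
and the acceptance script exercise these properties at the panel's natural
size (39 metabolites, two systems, ~200-peak samples) with 20 seeds for the
stochastic checks, sizes at which the full suite completes in well under a
minute.

## Known limitations

* Class labels are path-determined under the default grammar; exotic custom
  rules fall back to a generic `alias +RxN` label.
* The multiset view of paths checks feasibility on the final formula;
  rule sequences that are only transiently infeasible do not arise with
  element-count deltas of this size.
* Positional/stereochemical isomer assignment is out of scope — isomers are
  separated by retention time only, exactly as in the source study.
* Negative mode, multiply charged ions and phase-II conjugates are not
  modelled; none occur in this chemistry.
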