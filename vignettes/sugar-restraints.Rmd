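---
title: "Conformation-dependent restraints for nucleic-acid sugars: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation-dependent restraints for nucleic-acid sugars: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarcdl)
```

## The problem

Crystallographic and cryo-EM refinement of nucleic acids at ordinary
resolution needs stereochemical restraints: target values and standard
deviations for bond lengths and angles, applied as penalty terms. Classic
dictionaries assign one fixed target per parameter (split at most by
ribose vs 2'-deoxyribose). The sugar moiety, however, is the most flexible
part of the nucleotide: its covalent geometry shifts measurably with the
ring pucker, with the glycosidic torsion chi, and with the exocyclic
torsion gamma. A conformation-dependent library assigns each sugar targets
evaluated at its *own* conformation. This package implements such a
library for the (deoxy)ribose moiety: measurement, classification,
dictionary lookup/evaluation, restraint emission for REFMAC, PHENIX and
SHELXL, the statistical pipeline that derives such dictionaries from
fragment-geometry tables, and a validation (scoring) layer.

## Conformational variables and conventions

**Pseudorotation.** The five endocyclic torsions are indexed
nu0 = C4'-O4'-C1'-C2' through nu4 = C3'-C4'-O4'-C1', with the model
nu_j = tau_m * cos(P + 144(j - 2)). P (phase, degrees in [0, 360)) selects
which atoms pucker out of plane; tau_m (amplitude, degrees, typically
25-45) measures how much. We solve for (P, tau_m) by linear least squares
over all five torsions (the cosine model is linear in
tau_m*cos P and tau_m*sin P, and the design columns are exactly
orthogonal), rather than by the two-torsion closed form: the
least-squares route degrades gracefully under ring-closure noise, and the
two conventions agree exactly on noiseless rings. A flat ring (tau_m = 0)
is reported as P = 0 by convention and flagged.

**Classification windows.** C3'-endo is 0 <= P <= 36, C2'-endo is
144 <= P <= 190, everything else is "Other". The windows are applied
verbatim, including the upper bound of 190 degrees that exceeds the
conventional half-range; values in (36, 144) and (190, 360) fall in
"Other". The chi rotamer is syn iff |chi| <= 90 (boundary inclusive as
printed), anti otherwise. Gamma rotamers are gauche+ (60 +/- 30),
gauche- (-60 +/- 30) and trans (180 +/- 30, spanning the +/-180 wrap);
gamma outside all three windows is classified "other".

**Atom paths.** chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
pyrimidines (the standard IUPAC definition); gamma is O5'-C5'-C4'-C3'.
Hydrogens are ignored throughout. Terminal status of a sugar is decided
covalently: an O3'/O5' atom with no phosphorus within 1.8 A is terminal.
Each alternative conformation (altloc) yields an independent fragment and
independent restraints. Only the first model of a multi-model file is
read. All internal math is in Angstrom and degrees.

## The dictionary

The dictionary file (`inst/extdata/sugar_dictionary_reconstructed.tsv`)
is a flat, human-readable table: one row per (parameter, conditioning
cell), with conditioning columns (sugar, base, pucker, chi rotamer,
gamma rotamer, terminal state; `any` = unconditioned), one of three
functional forms, a sigma, a sample size N, and a provenance
(`this-work` for the conformation-dependent library, `parkinson` for the
1996-style single-value reference used as comparison baseline).

* `fixed`: a constant target (A or degrees).
* `linear_tau`: slope * tau_m + intercept, used for the endocyclic ring
  angles. All slopes are negative (larger pucker amplitude closes the
  ring angles), between -0.241 and -0.088 deg/deg, so a 20-degree change
  in tau_m moves a target by up to 4.8 degrees. tau_m outside roughly
  [20, 50] degrees is evaluated but flagged as extrapolation.
* `periodic_chi`: offset + amp1*cos(2*chi + phase1) + amp2*cos(chi +
  phase2). The dominant harmonic has a 180-degree period; for the two
  glycosidic bond lengths (C1'-N, C1'-O4') amp2 = 0 and the curve is
  strictly 180-degree periodic with extremes near chi = +/-90 (the bond
  is shortest where the base is orthogonal to the sugar and lengthens
  toward syn/anti). Amplitudes lie in [0.007, 0.018] A, i.e. a
  max-minus-min swing of up to 0.036 A. The second harmonic exists to
  encode the syn/anti asymmetry of the four glycosidic-link *angles*,
  which are periodic but not strictly sinusoidal; dictionaries produced
  at run time by the derivation pipeline may instead carry tabulated
  `curve` targets (dense chi grid with periodic interpolation and a
  curve-local sigma).

**Provenance of the numbers.** The `basis` column makes the epistemic
status of every row explicit. `reported` rows carry values documented
verbatim in the source analysis's running text (the terminal
C4'-C5'-O5' pair 111.5/110.6 degrees, the terminal C5'-O5' bond
1.421 A); `derived` rows are arithmetically implied by that text (e.g.
the 1.440 A reference C5'-O5', 0.019 A longer than the terminal value;
the terminal C3'-O3' range endpoints 1.414/1.422 A; the extreme slope
-0.241 and amplitude 0.018); `representative` rows are **synthetic
placeholder coefficients**: chemically plausible values consistent with
every documented constraint (group structure, slope range and sign,
amplitude envelope, extreme positions, terminal offsets of 0.1-0.9
degrees) but *not* transcribed from the published tables, which were not
available in machine-readable form when this package was assembled.
Users with access to the published tables can replace the file — the
format is stable and documented in its header — without touching code.

**Lookup semantics.** Lookup filters rows by parameter and matches each
conditioning column against the context (`any` matches everything),
returning the most specific row. Terminal variants of the five
O3'/O5' parameters override the non-terminal ones when the corresponding
flag is set. Non-terminal C3'-O3'/C5'-O5' *bonds* belong to the
phosphodiester moiety, whose dictionary is out of scope here; interior
sugars therefore get no restraint for them (the associated *angles* are
restrained). A gamma rotamer outside all windows would leave a sugar
unrestrainable under a gamma-split parameter; instead lookup falls back,
with a warning, to a pooled target computed at load time as the
N-weighted mean of the gamma-split groups with the pooled (between +
within group) standard deviation. We chose pooling over nearest-window
assignment because it never pretends to more conformational knowledge
than the model supports.

## The derivation pipeline

`build_dictionary()` re-derives a dictionary from a fragment-geometry
table (one row per sugar-base fragment: quality metadata, conformational
variables, one column per measured parameter).

1. **Quality filter** (`quality_filter()`): keep rows with R-factor
   <= 8.5 % (inclusive) and mean C-C bond e.s.d. < 0.01 A (strict).
   Disordered structures are *retained*: discarding them shrinks the
   sample and inflates the standard error of the mean more than it
   helps, because disorder usually sits outside the queried fragment.
   `sampling_diagnostics()` reports the SEM/SD trade-off across R
   cutoffs; it is a report, not a decision gate.
2. **Robust outlier rejection**: modified Z-score
   M = 0.6745 (x - median) / median|x - median| within each sugar-base
   class, |M| > 3.5 flags an outlier, and the *entire structure* is
   removed when any of its parameters is flagged. When the median
   absolute deviation is zero, the formula's limit applies: any value
   off the median is flagged.
3. **Discrete grouping search**: for each parameter, each candidate
   factor (sugar type, base type, pucker class, chi rotamer, gamma
   rotamer) is tested by pairwise two-sided Welch t-tests (alpha = 0.05,
   no equal-variance assumption); a factor is accepted when strictly
   more than half of its level pairs differ significantly. When two or
   more factors are accepted, the two with the smallest p-values are
   combined only if, among the combination cells, the majority of
   *stratified* pairs (cells differing in one factor with the other
   held fixed, e.g. ribose C2'-endo vs ribose C3'-endo) are significant
   *for each factor separately*; otherwise the single best factor wins.
   The stratification is essential: with the study's unbalanced class
   composition, unstratified pair counting lets a confounded factor ride
   on another factor's signal. Welch p-values are deliberately
   uncorrected for multiple testing (matching the derivation procedure
   this pipeline re-implements); the report records the number of tests.
4. **Functional screen**: within the accepted groups, each continuous
   variable (tau_m, chi, gamma) is screened by Spearman rank correlation
   (pass: |rho| > 0.5 and p < 0.05, average ranks for ties), with the
   majority rule across groups. For the cyclic variables the screen is
   evaluated within strata additionally split by that variable's own
   rotamer: a periodic dependence is monotone only within a rotamer
   range, so the raw statistic is blind to it on bimodal torsion
   samples. An accepted dependence on a torsion *drops* the discrete
   rotamer split of that same torsion — the continuous form subsumes it
   (this is why the glycosidic bond is a function of chi rather than a
   syn/anti pair of constants).
5. **Fitting**: tau_m relations are fitted by evidence-maximizing
   Bayesian ridge regression (MacKay fixed-point updates; equivalent to
   a Gaussian process with a linear kernel), reported as slope/intercept
   with the residual predictive sigma. Torsion relations are fitted by
   Gaussian-process regression with an exp-sine-squared kernel
   (candidate periods 180 and 360 degrees) plus a white-noise kernel;
   data are mean-normalized internally; hyperparameters (period,
   length-scale in {0.7, 1.5}, signal variance in {0.3, 1} x var(y),
   noise level on a log grid spanning 1e-7..1e7 refined around the
   sample SD) are selected by maximizing the log marginal likelihood.
   The predictive mean/SD is tabulated on a 2-degree grid; the stored
   sigma is curve-local (the grid median), a choice flagged in the
   report since pooling is equally defensible. A failed hyperparameter
   search falls back to a flat widest-noise curve and is flagged.
   Groups smaller than 5 are merged into an unconditioned parent row
   and flagged.

## The synthetic generator and the closed loop

`generate_synthetic_table()` emulates a curated small-molecule fragment
export: per-class sample sizes 130 (ribose-purine), 51
(deoxyribose-purine), 84 (ribose-pyrimidine), 167
(deoxyribose-pyrimidine); pucker mixtures tied to sugar type (riboses
62 % C3'-endo, deoxyriboses 60 % C2'-endo, both with an "Other" tail);
tau_m ~ N(38, 5) truncated to [22, 48]; chi 85 % anti ~ N(-120, 25) and
15 % syn ~ N(45, 25); gamma 58/25/13/4 % gauche+/trans/gauche-/other;
R-factors and sigma(C-C) within the selection thresholds (optionally a
fraction violating them, to exercise the filter); parameter values drawn
from a generating dictionary evaluated at each row's own conformation
plus Gaussian noise at the stored sigma; optional planted gross
outliers. What it does **not** emulate: correlations between parameters
beyond their shared conformational dependence, experimental-error
heteroscedasticity across structures, chemically coupled ring-closure
constraints among the five endocyclic angles, or crystal-packing
pressure on the conformer mixture. Passing closed-loop tests therefore
demonstrate that the statistics recover what they assume — not that the
assumptions hold for real crystallographic data.

`closed_loop_recovery()` generates a table from a known compact
dictionary (a fixed bond, a pucker-split bond, a gamma-split bond, the
chi-periodic glycosidic bond by base type, and a tau_m-linear endocyclic
angle conditioned on pucker only), re-derives the dictionary, and
compares: fixed targets by recovery error in units of the generating
group's SEM, linear targets by relative slope error, periodic targets by
the relative error of the curve's max-minus-min swing.

**Why three seeds.** The recovery error of a group mean divided by its
SEM is a standard normal variable whatever the sample size, so a single
replication of "every group within 2 SEM" over ~12 groups fails a large
fraction of perfectly healthy runs. The tests therefore average the
recovery error over three fixed seeds and require the average within
2 SEM per fixed group, the family-average slope error <= 15 % (each
group <= 30 %), and the family-average periodic swing error <= 20 %
(each group <= 40 %). The smallest linear group (the "Other" pucker
class, n = 76) has a per-replication slope standard error of ~16 % of
its true slope — per-group recovery at 15 % is underpowered there by
construction, which is worth knowing when reading real derivations too.
One replication (432 fragments) takes about two seconds on one CPU; the
whole suite stays within a few minutes.

**A power finding.** At representative amplitudes (max-minus-min of
3.5-4.3 degrees) and sigmas (1.3-1.4 degrees), the |rho| > 0.5 screen
does not detect the two-harmonic chi dependence of the glycosidic-link
*angles*: the pipeline then legitimately resolves those angles into
chi-rotamer groups instead. Curve recovery for such angles is verified
at the fitting level (`fit_functional()`), where a well-spread torsion
sample recovers the two-harmonic curve to an RMSD well under the noise
level; the discovery-level periodic closed loop uses the glycosidic
bond, whose monotone-within-rotamer signal the screen does see.

## Writers

Printed precision is fixed at 3 decimals for Angstrom and 2 for degrees,
matching the dictionary's resolution; output ordering is deterministic
(chain, residue, insertion, altloc, kind, parameter), so repeated
invocations are byte-identical. Restraints are regenerated from scratch
on every invocation — group assignments and functional targets change as
a model's torsions move during refinement (of order 10 % of assignments
per cycle in practice), so the generator is stateless by design and
should be re-run before each refinement round.

* **REFMAC**: one `exte dist`/`exte angle` keyword line per record, with
  `alte` selectors for alternative conformations.
* **PHENIX**: a `refinement.geometry_restraints.edits` block with
  bond/angle edits and `altid`/`icode` qualifiers.
* **SHELXL**: bonds as `DFIX_n`, angles as `DANG_n` 1-3 distances via
  the law of cosines, d13 = sqrt(b1^2 + b2^2 - 2 b1 b2 cos theta), with
  the sigma from first-order propagation of the two bond sigmas and the
  angle sigma. An angle whose flanking bond targets are not both in the
  record set cannot be encoded: the glycosidic-link angles (their
  base-ring bond belongs to the nucleobase dictionary) and, on interior
  sugars, the O3'/O5' angles (phosphoester bonds belong to the
  phosphodiester dictionary). The writer either raises an error naming
  the missing bond or, in the command-line driver, skips them with a
  warning. Whether a native-angle or DANG encoding is preferable is a
  SHELXL modelling choice; DANG is its native mechanism and was chosen
  here.

The emitted dialect details not fixed by any published source are pinned
by golden files in the test suite and follow the programs' public
manuals.

## Validation scoring

`score_model()` evaluates every applicable target at each fragment's own
(P, tau_m, chi, gamma) — not at group means; this is precisely what
makes a conformation-dependent library score better than a fixed one —
and reports per-record deviations plus RMSD(bonds) and RMSD(angles).
The default "well-ordered" filter keeps full-occupancy,
single-conformation fragments only and can be switched off.
`compare_dictionaries()` runs Wilcoxon signed-rank tests on the paired
absolute deviations of two dictionaries over the same records (bonds and
angles separately); identical reports are the degenerate no-difference
case, reported with p = 1. All dictionary parameters enter the RMSD,
including the glycosidic-link angles into the base.

The re-refinement layer (running REFMAC/PHENIX/SHELXL on deposited
structures and comparing R/R_free) is explicitly out of scope; the
scoring layer reproduces only the restraint-vs-model comparison. An
external ultrahigh-resolution reference structure is not bundled with
the package, so the external-structure acceptance check requires the
user to download the coordinate file; everything else runs from built-in
code paths.

## Known limitations

* Dictionary rows labelled `representative` are synthetic placeholders,
  not literature values (see "Provenance of the numbers" above).
* The fragment builder (`build_nucleotide()`) is a geometric scaffold:
  it reproduces requested torsions and bond lengths exactly but closes
  the furanose ring only approximately, and chains built with
  `build_chain()` are connected for terminal-detection purposes, not
  energetically sensible.
* mmCIF support covers the standard `atom_site` loop via bio3d's reader;
  exotic dialects are untested.
* No symmetry expansion, no anisotropic displacement handling, and only
  the first model of multi-model files.
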