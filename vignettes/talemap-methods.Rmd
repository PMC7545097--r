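---
title: "Methods: cross-link mapping and quantitative assays for TALE complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-link mapping and quantitative assays for TALE complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talemap)
```

`talemap` re-implements, as tested and seeded code, the computational side
of a cross-linking mass-spectrometry (XLMS) study of the PREP1–PBX1 and
MEIS1–PBX1 heterodimers, together with the binding and imaging
quantifications that accompany such a study. This vignette documents the
models, the conventions and the genuinely open design choices; the README
shows the user-facing workflow.

## Cross-link identification model

A BS³ cross-link connects two lysine side chains within the ~11 Å reach of
the spacer. After double digestion (Glu-C, then trypsin) a cross-linked
species appears as a *peptide pair* with one link position per peptide, or
as a single *looped* peptide carrying both positions. Each search-engine
record therefore holds: the peptide(s), the 1-based in-peptide link
position(s), protein assignments, an E-value, a replicate label and
optionally fragment-ion annotations (`xlink_ids()`).

**Curation** (`curate_identifications()`) keeps a record iff

* E-value `< 1e-3` — strict inequality, matching the stated threshold;
* each cross-linked peptide shows at least 4 *consecutive* ordinals in its
  b series or in its y series. The two series are evaluated independently
  (a run may not mix b and y ions) — that is our reading of "4 consecutive
  b or y ions", and the stricter of the two plausible readings;
* the fraction of assigned spectrum peaks is `> 0.5`. The source protocol
  requires "the majority" of ions assigned without quantifying it; we adopt
  a strict majority and expose the fraction as a parameter;
* every linked position falls on a lysine. BS³ also reacts with the protein
  N-terminal α-amine, so a link at peptide position 1 on a non-K residue
  can be accepted behind `allow_nterm = TRUE` (default off: the curated
  tables report only K–K links).

Records without ion annotations (e.g. transcribed summary tables) are
rejected unless `permissive = TRUE`, in which case they pass flagged
`"uncurated"`.

**Mapping** (`map_to_residues()`) converts in-peptide positions to absolute
residues as `peptide_start + position − 1` after locating the peptide in
its protein; a claimed absolute residue, when present, must agree exactly
and disambiguates peptides occurring at several offsets.
`infer_peptide_offsets()` audits a whole table: all records sharing a
(protein, peptide) pair must imply one start offset. On the shipped
fixtures the audit reports zero contradictions.

**Classification and collapse.** A record is a `loop` if single-peptide,
`inter` if its proteins differ, `intra` otherwise — exhaustive and mutually
exclusive. Unique links are residue pairs under a canonical order
(protein name, then residue), so `(A,87)–(B,55)` and `(B,55)–(A,87)` are
one link; a loop link's two positions are unordered. Deduplicating at the
residue-pair level (not the peptide-pair level) is what reproduces the
published "non-redundant" counts, and is the convention adopted
throughout. A link is drawn bold when its evidence spans ≥ 2 distinct
replicate labels; the flag is monotone under added evidence.

### Scaffold sequences

Native full-length sequences are not part of the shipped data. Instead,
`build_scaffold()` reconstructs for each protein the minimal sequence
consistent with the identification tables: every peptide is written at the
offset implied by its claimed residues, individually documented residues
(the heptad paragraphs name e.g. L63/L66/L70/K73 in PREP1 HR1) are added,
conflicts raise an error, and all unconstrained positions carry a filler
`G`. The shipped `scaffold_synthetic.fasta` is generated this way, padded
to the full protein lengths (PBX1 430, PREP1 436, MEIS1 390). Scaffolds
are explicitly labelled synthetic; they support residue mapping, register
annotation over the constrained intervals and diagram layout, but no
sequence-level inference elsewhere. A test verifies that every fixture
peptide occurs exactly once in its scaffold, which is what makes mapping
unambiguous.

## Heptad registers and digestion

Heptad positions a–g cycle with period 7 from an anchor residue of known
phase (`assign_heptad()`); the a/d positions form the hydrophobic face of
an amphipathic helix (`hydrophobic_face()`). The anchors used in the tests
are the published ones (PREP1 HR1: a at 63; HR2: a at 122, hence phase c
at 117; PBX1 43–56: a at 43; PBC-B: a at 201).

`digest_in_silico()` cleaves C-terminally to K/R (trypsin) and E (Glu-C).
Two conventions are configurable because the protocol leaves them open:
cleavage before proline is blocked by default (the common search-engine
default), and Glu-C cleavage after D (a buffer-dependent specificity) is
off by default. Cross-linker-modified lysines are passed as
`blocked_sites` and never cleaved — this is required to produce peptides
such as `KTVLSIR` that *begin* with the linked lysine. With zero missed
cleavages the peptides tile the sequence; the missed-`k` set equals all
merges of ≤ `k+1` adjacent fully-cleaved peptides (tested against that
oracle); up to 5 missed cleavages mirror the search setting.

The default domain tables (`default_domain_tables()`) place HR1/HR2/HR3,
PBC-A/PBC-B and the homeodomains. Only the helical-stretch boundaries are
printed in the source (HR1 63–73, HR2 117–132, HR3 242–252; PBX1 stretches
43–55, 77–90, 105–113, 197–211); the enclosing block boundaries are
conventional and the tables carry an `approximate` attribute.

## One-site binding and TR-FIA statistics

ELISA dose series follow `y = baseline + B_max·x/(K_D + x)`. The published
dose span 0.23 nM – 0.5 µM equals 3⁷, so the generator's default ladder is
an 8-point 3-fold dilution series (`elisa_doses()`), in triplicate.
`fit_one_site()` minimises squared error by Levenberg–Marquardt from 12
log-spaced K_D starts spanning the dose range ± 2 decades, keeping the
best converged solution; `se_kd` comes from the fit curvature, and
estimates outside dose span × [10⁻², 10²] are flagged `extrapolated`. The
baseline is fixed at 0 by default: the assays subtract a matched GST
control (`subtract_control()`, negatives kept with a warning), after which
a "one-site binding" model has no offset; `fit_baseline = TRUE` frees it.

The simulation noise model is multiplicative unit-mean log-normal with a
given coefficient of variation (`synth_binding_curves()`), the standard
error structure of plate immunoassays; the protocol states none. With 5 %
noise the median of 25 fitted K_D values recovers 18 nM and 80 nM truths
well within the reported ± 4 / ± 17 nM.

TR-FIA signals are normalised per experiment to that experiment's
wild-type signal (wild type ≡ 1), then summarised across experiments by
the mean and the *population* standard deviation (the `STDEV.P`
convention). Mutants are compared to wild type with a pooled-variance
two-sample t-test, one-tailed in the mutant-below-wild-type direction —
the loss-of-binding hypothesis under which the star thresholds
0.05/0.025/0.01/0.005/0.001 (strict `<`) were defined. Two degenerate
conventions are documented in `ttest_homoscedastic_onetail()`: equal
samples with zero pooled variance give p = 0.5; unequal means with zero
variance give 0 or 1 by sign.

## Imaging procedures

Both quantifications operate on plain numeric matrices
(`image_field()`).

* **Rolling-ball background** is computed as the grayscale opening of the
  image by a flat disc of the given radius (the flat-disc approximation of
  the rolling ball). Morphology is delegated to EBImage after an exact
  affine rescaling to [0, 1] (erosion/dilation commute with positive
  affine maps); windows are clipped at the borders. The background never
  exceeds the image, so corrected intensities are non-negative, and the
  implementation agrees with a brute-force min/max opening to well below
  one intensity unit.
* **Thresholds.** Otsu maximises between-class variance; Huang minimises
  the Huang–Wang fuzzy entropy with membership
  `u(g) = 1/(1 + |g − μ_class(g)|/C)`, `C = g_max − g_min`, and cost
  `Σ h(g)·S(u(g))`. Integer images use their native levels; continuous
  images are binned (256 bins by default). The returned threshold is the
  midpoint between the optimal split's adjacent occupied levels, so it
  strictly separates the classes; ties resolve toward the lowest
  threshold. Both equal exhaustive searches over all candidate thresholds
  (tested on random 8-bit images), and Otsu additionally agrees with
  EBImage's implementation.
* **Find Maxima** follows prominence/noise-tolerance semantics: a regional
  maximum is accepted iff no path from it reaches a strictly higher pixel
  without first descending below `value − tolerance`. The global maximum
  has no higher ground; by the topographic convention its prominence is
  its height above the image minimum, which must likewise exceed the
  tolerance (this is what makes a flat-plus-noise field return no foci).
  Equal-valued plateaus merge to one point at the centre of mass, rounded
  to the nearest plateau pixel with ties toward the smallest row then
  column. The implementation is a descending-level union-find; tests
  compare it against a literal breadth-first-search oracle of the path
  definition.
* **Nucleus segmentation** chains background removal → Gaussian blur →
  Huang (or Otsu) threshold → 8-connected components → hole filling →
  minimum-area filter. Defaults: rolling radius 50 px, σ = 2 px, minimum
  area 200 px² — none are printed in the source protocol; these are
  typical Fiji settings at ~0.3 µm/px. A guard refuses to threshold
  images whose processed dynamic range is below `min_contrast` (default
  5), since histogram thresholds on blank fields would otherwise split
  noise. Connected components are computed in-package because the
  available labelling routine is 4-connected.
* **PLA counting** (`quantify_pla()`) detects foci on the
  background-removed red channel (optionally lightly smoothed,
  `smooth_sigma = 1`, which suppresses single-pixel noise without moving
  spot centres) and partitions them by the nucleus mask; totals always
  partition the focus list. **N/C ratios** (`nc_ratio()`) divide the mean
  nuclear signal by the mean cytoplasmic signal per cell; cytoplasm
  regions are supplied as masks (the analogue of the protocol's
  hand-drawn regions) or derived as a dilation ring minus all nuclei.
  Condition-level values are normalised to the wild-type *median*
  (configurable to the mean; the source does not say which centre it
  used).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a single integer
seed (the global RNG state is restored afterwards).

* `synth_protein_pair()` draws random sequences with a fixed lysine count,
  regenerating until every fully-cleaved peptide of length ≥ 5 is unique
  within its protein — mirroring the property that makes real tables
  mappable.
* `synth_xlink_truth()` / `synth_xlink_dataset()` plant inter/intra/loop
  links on lysines and emit 1–3 records per link across two replicates
  with passing E-values (log-uniform 10⁻⁸–10⁻⁴), full ion series and 70 %
  assigned peaks; decoys each violate exactly one curation rule (E-value
  log-uniform 10⁻³–1, a broken ion run, 40 % assigned, or a non-lysine
  position). Curation must recover precisely the planted set — the
  round-trip is exact by construction, which is the point: it tests the
  plumbing, not the discriminative power of the rules on real spectra.
* `synth_pla_image()` renders elliptical nuclei and Gaussian foci
  (σ = 1.5 px, amplitude 100 over a linear background gradient, noise
  σ = 4 on a 160×160 field) with margins and a minimum focus separation of
  10 px that keep nuclear/cytoplasmic assignment unambiguous.
  `synth_nc_image()` builds concentric nucleus/cytoplasm ellipse pairs
  with specified compartment means, returning the exact region masks.

These fields emulate the *statistical* structure the pipeline assumes —
compact nuclei, point-like foci, smooth background — not real microscopy:
no point-spread function beyond the Gaussian spot, no uneven illumination
beyond a linear ramp, no touching nuclei, no autofluorescence. Passing the
recovery tests therefore demonstrates correctness of the measurement code
under its stated assumptions, not robustness to every real-world artefact.
Likewise the identification generator does not simulate spectra, retention
times or FDR structure; it exercises parsing, curation logic, mapping and
replicate bookkeeping.

## Numerical choices and problem sizes

Strict inequalities are used wherever the conventions state thresholds
(E-value, majority fraction, stars, noise tolerance). Threshold ties break
toward the lowest candidate; plateau ties toward the smallest row/column;
canonical link order by protein name then residue. The test-suite problem
sizes (100 random 8-bit images for threshold oracles, 50 random 64×64
rasters for the maxima oracle, 50 synthetic PLA fields per noise regime,
25 simulated curves per K_D condition) were chosen to exercise the
properties at, in total, a few minutes of runtime; all are plain loops a
user can scale up.

## Known limitations

* The curation of transcribed summary tables is necessarily `permissive`:
  printed tables carry no E-values or ion annotations.
* `fit_one_site()` reports the Wald standard error of K_D; for strongly
  correlated (K_D, B_max) at sparse dose coverage a profile interval would
  be more honest.
* Loop-link peptides are required to contain both linked lysines within
  one digest peptide (with both sites blocked); loop links spanning longer
  ranges than the allowed missed cleavages cannot be planted.
* The SVG map draws inter-protein links as straight chords between bars
  and intra-protein links as arcs; visual grammar beyond bold/thin and
  class colour is style configuration, not data.
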