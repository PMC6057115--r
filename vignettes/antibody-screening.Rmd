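---
title: "Probabilistic punctum and synapse detection for antibody screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic punctum and synapse detection for antibody screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

## The problem

Array tomography images immunofluorescently labeled serial ultrathin
sections (~70 nm) of plastic-embedded brain tissue and aligns them into 3D
stacks. Synaptic proteins appear as *puncta* — compact blobs, usually under
1 µm across, that span several consecutive sections when the target protein
is abundant on its synaptic side. Evaluating whether a new ("candidate")
antibody labels its intended synaptic target means answering quantitative
questions across many image stacks: how many puncta does it produce, how
large and how variable are they, and what fraction of them sit at synapses
marked by previously validated ("reference") antibodies?

`synscreen` answers these questions with a query-based probabilistic
detector. The user states the expected target-synapse composition — minimum
punctum size per channel, and whether the candidate should be *colocalized*
with each reference (same synaptic side, same in-plane location) or
*adjacent* to it (opposite side, nearby in 3D) — and the package turns each
channel into probability maps, combines them, and derives per-antibody
performance measures. No training annotations are required, which is what
makes the approach practical for screening dozens of candidates.

## The detection model

### Foreground probability

The entire channel is modeled as Gaussian background noise with the signal
as outliers. The background parameters are the channel-wide intensity mean
and standard deviation (population convention, dividing by *n*: the model
treats the whole channel as the noise population; at image scale the
difference from the sample convention is negligible, but fixing one makes
runs reproducible bit for bit). The probability that a voxel is foreground
is one minus its background probability, computed as the lower-tail normal
CDF of its z-score:

$$p_\mathrm{fg}(I) = \Phi\!\left(\frac{I - \mu}{\sigma}\right).$$

This reading was a genuine design choice: "one minus the background
probability" could also be a two-sided tail. The CDF form is used because it
is monotone in intensity, equals 0.5 exactly at the background mean, and
treats only *bright* outliers as signal, which is what immunofluorescence
puncta are. It also makes the map invariant to adding a constant to the
whole channel (the model is re-estimated), so inter-session offsets in
camera baseline do not matter. A constant channel has zero variance and is
rejected (`degenerate background`) rather than silently mapped to an
uninformative all-0.5 map.

### Minimum in-plane size: window products

To require a minimum 2D blob size, the foreground probabilities inside a
window of that size (default 2 × 2 pixels = 0.2 × 0.2 µm at 100 nm pixels)
are multiplied. Window placement needed a decision, since an even window has
no central pixel: every voxel receives the **maximum product over all
windows that lie fully inside the slice and contain it**. This has two
consequences we consider the correct behavior: every voxel of a qualifying
blob is stamped with the blob's full probability (so later thresholding
yields the blob, not its inner erosion), and a blob must have *full* minimum
support — windows are never clipped at slice borders, so partial blobs at
the edge of the field cannot score as if they were complete.

Products are accumulated in log space and exponentiated once; results equal
the direct product to within 1e-12 (verified against brute-force
enumeration), and large windows cannot underflow.

### Minimum section span: consecutive-slice products

The same rule is applied along z: at each in-plane position, blob
probabilities over every run of `span` consecutive slices are multiplied and
each voxel takes the maximum over the runs containing its slice, so both
slices of a 2-slice punctum carry its probability. A span of 1 is the
identity, bit for bit. The span requirement is what rejects single-slice
specks — dust, nonspecific binding, shot noise — because a speck contributes
a high probability on one slice only, and the product with its neighboring
background slices stays far below threshold.

### Thresholding and segmentation

The punctum probability map is thresholded at 0.9 (a global default, held
fixed across a screening run, exposed as a parameter) and the surviving
voxels are labeled as 26-connected 3D components; puncta are compact blobs
spanning slices, so the most permissive standard connectivity is
appropriate. Thresholding can split one punctum in two where a single
interior voxel dips below threshold, which inflates punctum counts and can
push the target specificity ratio above 1. The remediation is a single
binary closing with a 3 × 3 in-plane structuring element applied slice-wise
before labeling — enough to repair one-voxel splits without bridging
distinct puncta on neighboring slices. It is on by default and switchable
off; reports carry both the raw and the remediated ratio.

### Synapse queries

A reference channel is processed with the same punctum detector (its own
minimum sizes), then converted into an **association factor**: each voxel
takes the maximum reference punctum probability within the relationship's
search neighborhood. The synapse probability map is the candidate punctum
map multiplied voxel-wise by the association factor of every reference — a
probabilistic AND, which is the natural combination for a query of the form
"candidate AND reference1 AND reference2". Nothing is thresholded until
after this cross-channel association.

The neighborhood sizes follow the standard windows: 2 × 2 pixels for
colocalization and 6 × 6 for adjacency. Since even windows have no center,
the neighborhood is made symmetric with in-plane reach $\lfloor w/2 \rfloor$
pixels per axis — 1 px for colocalization, 3 px for adjacency. Symmetry is
not cosmetic: it guarantees that swapping candidate and reference under a
symmetric relationship leaves the detected count unchanged, a property the
test suite asserts. In z, colocalization stays on the same slice (reach 0:
both markers on the same synaptic side should overlap in-plane) while
adjacency reaches ±1 slice, because presynaptic and postsynaptic partners
may be captured on neighboring sections. Both reaches are configurable; the
z reach in particular can be raised for stacks with imperfect alignment.
Unlike the product windows, max neighborhoods are clipped at volume borders
— a maximum over a partial neighborhood is well-defined and clipping does
not inflate probabilities.

Each 26-connected component of the thresholded synapse map counts as one
target synapse; merged components are not split, so two candidate puncta
sharing one reference punctum within a single component count once. This is
the simplest consistent reading, and the alternative would require an
arbitrary splitting rule.

## The measurements

For a candidate channel under a query, the report contains:

* **Punctum density** — detected 3D puncta per µm³ of imaged tissue
  (voxel volume from the stated geometry; 0.1 × 0.1 × 0.07 µm = 7e-4 µm³
  by default). Zero means no puncta were found.
* **Punctum volume mean and SD** — in voxels, population SD. A large
  SD-to-mean ratio flags erratic labeling (occasional giant clusters among
  small puncta).
* **Target synapse density** — detected target synapses per µm³.
* **Target specificity ratio (TSR)** — synapses divided by candidate
  puncta: the fraction of candidate puncta at target synapses, from 1 down
  to 0. For zero detected puncta the TSR is reported as missing, not 0, so
  "no signal" is distinguishable from "no specificity"; screening runs over
  many candidates therefore never abort on an empty channel.

The identity `TSR × punctum density = target synapse density` holds
algebraically over a common volume and is asserted on every evaluation.

### Query sweeps and screening

`query_presets()` ships four stringency variants (minimum spans of candidate
/ reference in µm): Q1 0.07/0.07, Q2 0.14/0.07, Q3 0.14/0.14, Q4 0.21/0.07,
all keeping the 0.2 × 0.2 µm in-plane minimum. At 70 nm sections these are
1/1, 2/1, 2/2 and 3/1 slices. The single-slice Q1 admits specks and is the
least reliable; a two-slice candidate requirement (Q2) is the recommended
default for screening.

`rank_candidates()` first excludes candidates whose target synapse density
exceeds a user-supplied biological prior — expected synapse densities are
tissue knowledge (on the order of 1 per µm³ for excitatory and 0.15 per µm³
for inhibitory synapses in rodent neocortex), so the cutoff is a
configuration value, not a constant. A density far above the plausible
maximum reflects non-specific binding, and such a candidate must not win on
sensitivity. The survivors are ranked by TSR descending with target synapse
density as tie-break (then channel name, making the order total and
independent of input order); a combined score is deliberately not invented.

## The synthetic-data generator

Real array-tomography stacks are large, noisy, and lack voxel-level ground
truth, so validation uses a generator that emulates exactly the structure
the detector assumes:

* background noise drawn i.i.d. from N(mean, sd²), clamped at 0 and rounded
  to integer counts (defaults 1000 / 100, a realistic camera regime);
* puncta as separable blobs — an isotropic in-plane Gaussian profile
  (σ = 1 px, truncated to a 3 × 3 footprint) repeated identically over a
  3-slice extent, added at 10 background SD at the peak. This is the
  simplest shape consistent with "small compact blobs spanning sections";
  real puncta are neither separable nor flat in z, but the detector uses no
  shape model beyond minimum size, so this simplification does not favor
  it;
* planted relationships: a stated fraction of candidate puncta receives an
  adjacent reference partner (axis-aligned in-plane offset of 2–3 px,
  z offset 0–1) or a perfectly colocalized one; the rest are isolated.
  All object centers keep a minimum in-plane Chebyshev separation (12 px by
  default), which guarantees that isolated puncta fall outside every
  default search window — the planted adjacency fraction is then exactly
  the TSR an ideal detector should report;
* confounders: single-slice specks (contaminants that a 2-slice query must
  reject) and giant clusters (σ = 6 px, up to 4 slices) that reproduce the
  erratic-labeling regime where the volume SD dwarfs the mean.

Generation is deterministic given the spec's seed, and the ground-truth
table records every planted object with its type and partner link, so
precision and recall are computable by greedy one-to-one centroid matching.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: optical PSF blur and section-to-section
point-spread differences, misalignment between sections, spatially
structured background (autofluorescence gradients, tissue edges),
fluorescence bleed-through between channels, and realistic punctum shape
and intensity heterogeneity. Results on synthetic volumes bound the
method's behavior under its own assumptions; they are not a substitute for
expert inspection of real immunolabeling.

## Numerical and interface choices

* Physical sizes convert to grid units by round-half-up, floored at 1
  (0.2 µm → 2 px at 100 nm; 0.14 µm → 2 slices and 0.21 µm → 3 slices at
  70 nm). Round-half-up rather than banker's rounding keeps the stated
  equivalences exact.
* Voxel geometry always comes from configuration, never from TIFF tags.
  One grayscale multi-page TIFF per channel; intensities stored as 16-bit
  integers, probability maps as 32-bit float, label volumes as 16-bit.
* Binarization uses `value >= threshold`; thresholds must lie strictly in
  (0, 1).
* 3D connected-component labeling is a small compiled routine
  (stack-based flood fill, 26-neighborhood); labels are consecutive
  integers in order of first appearance, so runs are reproducible.
* The CLI (`exec/synscreen`) is a thin wrapper over exported functions;
  every run writes a `provenance.json` with the config echo, package
  version and seed, and identical inputs produce byte-identical CSV/JSON
  outputs.

## Validation problem sizes

The shipped tests and the acceptance script validate on 256 × 256 × 8
stacks (the size at which 50 well-separated default puncta fit comfortably)
for recovery, noise rejection and TSR-recovery checks, with smaller
64–192 px stacks for unit-level properties; brute-force oracle comparisons
run on 16 × 16 × 5 volumes where exhaustive enumeration is instant. These
sizes give exact, reproducible outcomes (precision = recall = 1, TSR equal
to the planted fraction to two decimals) in seconds per check.

## Known limitations

* The Gaussian background model is global per channel; strong illumination
  gradients would bias foreground probabilities (local or non-Gaussian
  background models are out of scope).
* Adjacency is isotropic in-plane and ±1 slice by default; heavily
  misaligned stacks need a relaxed z requirement (e.g. a single-slice
  candidate span), which weakens speck rejection.
* One connected component equals one punctum/synapse; genuinely touching
  synapses are counted once.
* The TSR conflates target biology with antibody specificity: a protein
  with substantial extrasynaptic pools will have a low TSR with a perfect
  antibody. Comparisons are therefore meaningful between antibodies against
  the same target, not across targets.
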