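# orgadyn

Quantitative analysis of organelle dynamics in multi-channel 2-D
fluorescence time-lapses: rule-based **fission-event detection** with an
observed-versus-chance marker colocalization test, **segmentation-based
morphometrics** for vesicular organelles and mitochondria, and two
**mobility** readouts (object tracking with mean straight velocity, and
first-frame autocorrelation decay). A seeded synthetic time-lapse
generator with exhaustive ground truth makes every stage testable by
parameter recovery, so the package is equally a measurement tool and a
benchmark harness for this class of assay.

It is aimed at cell biologists quantifying endosome / lysosome /
mitochondrial behaviour (for example under perturbations of ER-associated
actin regulators) who want the standard Fiji/Imaris-style readouts as
reproducible, scriptable R, with the statistics attached.

## The core procedures

**Fission scoring.** Per-frame instance masks are linked into a lineage
graph by temporal pixel overlap. A node with two or more daughters is a
fission event only if the parent persisted as a single object for at
least 30 s before the split and the daughters remain present and
mutually separate for at least 30 s after it; splits that re-merge
within the window ("kiss and run") are rejected. Each event's
constriction site is then scored for marker presence (any marker-mask
pixel within 0.25 um of the site during the 30 s before the split),
where the marker mask keeps the top 25% of the marker channel's
intensity range.

**Observed vs chance.** The chance that the marker hits a site
coincidentally is estimated two ways: the fraction of the organelle mask
overlapped by the marker mask (the conventional integrated-density
ratio), and a control-site randomisation that applies the identical
scoring operator to random organelle sites. Observed versus expected
counts are compared with a two-sided exact Fisher test

    p = sum of P_hypergeom(tables with the observed margins
                           no more probable than the observed table)

with an exact one-sample binomial test reported alongside.

**Morphometrics.** Vesicles: background subtraction, despeckle, contrast
stretch, median filter, moment-preserving (Tsai) threshold, 0.06 um^2
size filter, marker-controlled watershed, then per-object area, Crofton
perimeter and circularity `4*pi*A/P^2`. Mitochondria: adaptive local-mean
threshold, then skeleton length (Zhang-Suen thinning, diagonal steps
weighted sqrt(2)) and branches per micrometre.

**Mobility.** Mean straight velocity = start-to-end displacement / track
duration (tracks shorter than 10 s discarded); and the thresholded
Manders correlation M1/M2 between frame 1 and every later frame, whose
decay rate grows with organelle movement.

## Worked example

```r
library(orgadyn)

# a 5-minute synthetic movie: 18 organelles, strong fission-site
# marker enrichment (0.95) over a 20% background overlap
bundle <- run_pipeline(demo_config(seed = 1))
print(bundle)
```

```
<result_bundle>
  events: 18 detected, 18 marker-positive
  chance: mask 0.165, control-site 0.350; Fisher p = 2.97e-05, binomial p = 6.21e-09
  tracks: 36 kept, mean straight velocity 0.0032 um/s
  fission rate: 18.31 events/cell/5 min
  content hash: c4d4484e0646616bdb459d7d74891bd7
```

Reading: 18 fission events passed the persistence rules in the segmented
movie and every one had marker signal at its site, against a
control-site chance level of 35% - the Fisher comparison of observed
(100%) versus expected (35%) presence is decisive at p ~ 3e-5. The
organelles barely move (0.0032 um/s: the default simulation is the
docked regime), and `bundle$curve` holds the matching autocorrelation
curve. `write_result_bundle(bundle, "out/")` exports the per-object,
per-event, per-track and per-curve tables as CSV plus a JSON statistics
report.

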