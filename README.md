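# fluormargin

Full field-of-view quantification of indocyanine green (ICG) fluorescence
angiography video, and delineation ("margination") of regions with distinct
perfusion dynamics.

After an intravenous ICG bolus, tissue fluorescence rises rapidly as the
agent arrives (wash-in) and decays slowly as it clears (wash-out).
Differently perfused regions follow different time-intensity curves even
when a single frame looks uniform. `fluormargin` exploits this: instead of
tracking one hand-selected region of interest, it treats *every* foreground
pixel's intensity time-series as data and maps where the perfusion dynamics
change. It is aimed at researchers developing fluorescence endoscopy and
perfusion assessment tools who need a tested, scriptable implementation of
the pixel-clustering/correlation approach together with desk-scale
validation data.

## The algorithm

For a video with frames at times `t = 1..T`:

1. **Pre-process** — isolate the RGB channel carrying the fluorescence
   (fixed, or auto-selected by maximal temporal variance), then keep pixels
   whose temporal maximum exceeds a threshold (default 0.2 of the dynamic
   range), discarding background and non-dynamic areas.
2. **Cluster** — reduce the N×T trace matrix by PCA (up to 10 components or
   99% variance), run seeded k-means++ / Lloyd (default k = 4, best of 10
   restarts), and select the two clusters with the highest accumulated
   fluorescence (area under the cluster-center curve).
3. **Correlate** — score every pixel against each selected center curve
   with the normalized cross-correlation

   ```
   NCC(a, b) = 1/(T-1) * sum_t [(a_t - mean(a))/s_a] * [(b_t - mean(b))/s_b]
   ```

   (sample standard deviations; 1 identical, -1 negated, ~0 unrelated).
   The signed difference map `NCC_C1 - NCC_C2` splits the foreground into
   two regions (`> +eps`, `< -eps`) and a boundary band (`|.| <= eps`,
   default eps = 0.05).

Delineated masks are scored against references with the Jaccard index
`|A∩B| / |A∪B|`, resolving the arbitrary chamber numbering by best total
Jaccard per video.

The package also ships the optical-bench calculators used to characterize a
fluorescence imaging probe (angular field of illumination, Michelson
contrast / CTF with Rayleigh-criterion resolution conversion, fluorescence
SNR, dB attenuation), a single-ROI perfusion curve tracker with
wash-in/wash-out features, and a synthetic dual-chamber perfusion phantom
generator with ground-truth masks and noiseless curves.

## Worked example

Simulate the canonical dual-chamber phantom (480x640, 30 fps, 20 s; a
fast-flow and a slow-flow chamber with distinct wash-in/wash-out kinetics),
run the pipeline, and score it against the known ground truth:

```r
library(fluormargin)

ph  <- generate_phantom(default_phantom_config(seed = 0))
out <- margination_pipeline(ph$video, seed = 0)
out
#> <margination_pipeline> channel 1, 69054 foreground px, d = 2, k = 4, selected clusters 2, 4
#> <margination_result> chamber1: 34527 px, chamber2: 34527 px, boundary: 0 px (epsilon = 0.05)

evaluate_batch(list(out$result), list(ph$truth$chamber_masks))
#> <jaccard_report> 2 entries: mean 1.000 (min 1.000, max 1.000)
```

Reading the output: auto-selection picked channel 1 (red, where the
simulated NIR leak lives), thresholding kept the 69,054 chamber pixels, two
principal components captured the dynamics, and the two highest-AUC
clusters' NCC difference map split the foreground cleanly into the two
34,527-pixel chambers — each matching its ground-truth mask with Jaccard
1.000 on this noise level.

Optics calculators work on plain numbers:

```r
attenuation_db(1000, 52)    # 12.84 dB across the probe length
min_working_distance(20, 75) # 13.03 mm for a 20 mm target at 75 deg AFOI
min_resolvable_object(3.763) # 132.9 um
```

A thin command-line front end over the same functions lives at
`inst/cli/fluormargin` (subcommands `optics`, `simulate`, `segment`,
`evaluate`, `track-roi`).

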