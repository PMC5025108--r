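# icmpso

Automated sperm-head detection in phase-contrast microscopy frames, for
computer-assisted sperm analysis (CASA) pipelines that need per-frame head
positions before motility can be quantified. Frames of this kind are hard
on classical segmentation: illumination is non-uniform, contrast is low,
debris floats among the cells, and agglutinated sperm appear as merged
blobs.

## Method

The detector chains four stages, all implemented in this package:

1. **LoG pre-filtering.** The frame is convolved with a
   Laplacian-of-Gaussian kernel

   LoG(x, y) = −(1/πσ⁴) · [1 − (x²+y²)/(2σ²)] · exp(−(x²+y²)/(2σ²)),

   whose "Mexican hat" profile matches the dark, compact sperm head; the
   response is rescaled to [0, 1] and becomes the stimulus *S*.

2. **ICM segmentation.** An intersecting cortical model — a reduced
   pulse-coupled neural network with one feeding state *F*, dynamic
   threshold *E* and binary pulse *Y* per pixel —

   F′ = f·F + S + (W ∗ Y),  Y′ = [F′ > E],  E′ = g·E + h·Y′,

   is iterated *n* times from a high initial threshold (E₀ = 5); the pulse
   image after the final iteration is the segmentation. The 3×3 link
   kernel *W* (centre 1, 4-neighbours 0.01) lets fired neurons recruit
   similar-intensity neighbours, and the negative threshold amplitude *h*
   keeps fired neurons firing.

3. **PSO parameter tuning.** The four free parameters (f, g, h, n) are
   tuned per frame by a 50-particle global-best swarm (c₁ = c₂ = 2,
   inertia ω(t) = 0.9 − 0.5·t/t_max) that minimises the *feature mutual
   information* error |MI(frame, segmentation) − 0.07| in bits — 0.07
   being the information content of a correct head mask at this frame
   geometry (~60 heads ≈ 1% foreground).

4. **Feature extraction.** Connected regions are labelled; regions
   touching the border or lacking a head-dark core (intensity-based debris
   elimination) are discarded; region centroids are the reported head
   locations. Candidate segmentations are scored by the fitness *after*
   this cleanup, which is what makes the MI target selective for
   head-aligned masks.

A synthetic frame generator with exact ground truth (dark elliptical heads,
tails, debris, illumination gradients, agglutinated pairs, Gaussian noise)
and the four pixel-level evaluation metrics (accuracy, sensitivity,
specificity, precision) round out the package. See the methods vignette
(`vignettes/icm-pso-methods.Rmd`) for the full design rationale.

## Worked example

```r
library(icmpso)

# a synthetic 480x640 frame: 60 heads, tails, debris, illumination
# gradient, Gaussian noise (sd 0.02), with exact ground truth
scene <- generate_scene(scene_spec(noise_sigma = 0.02), seed = 1)

# the full detector: LoG -> per-frame PSO tuning -> ICM -> features
res <- segment_frame(scene$image, swarm = swarm_config(seed = 1))

res$params
#> ICM parameters: f = 0.8143, g = 0.4539, h = -4.8825, n = 3, E0 = 5
nrow(res$centroids)
#> [1] 60
res$optimization$best_fitness      # |MI - 0.07| of the returned mask
#> [1] 0.00569
res$optimization$best_mi           # achieved MI, bits
#> [1] 0.06431

# pixel-level quality against the generated ground truth
seg_metrics(confusion(res$mask, scene$mask))
#>    accuracy sensitivity specificity   precision
#>      0.9996      0.9870      0.9997      0.9655

# object-level: every planted head recovered, nothing spurious
match_detections(res$centroids, scene$centroids,
                 radius = scene$heads$major)[c("matched", "spurious")]
#> $matched
#> [1] 60
#> $spurious
#> [1] 0
```

The tuned parameters say: moderate feeding decay (f = 0.81), threshold
decaying at g = 0.45 from E₀ = 5, so after n = 3 iterations only stimuli in
the head band have out-raced their threshold — and the strongly negative
h = −4.9 keeps every recruited head pixel firing. The mask matches the
ground truth to 96.6% precision and 98.7% sensitivity; all 60 heads,
including the agglutinated pairs, come out as separate centroids.

A command-line front end with the same defaults ships in `inst/cli/`:

```sh
inst/cli/icmpso synth    --out frames --count 5 --seed 1 --noise 0.02
inst/cli/icmpso segment  --in "frames/image_*.png" --out detections --seed 1
inst/cli/icmpso evaluate --pred "detections/*_mask.png" \
                         --truth "frames/mask_*.png" --out metrics.json
```

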