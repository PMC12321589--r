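# mrgpet

Anatomically guided reconstruction of brain PET data with a co-registered MR
prior, plus everything needed to evaluate it without scanner access: a
digital Hoffman-type brain phantom, a parallel-beam Poisson forward model
with dose reduction by count thinning, and the standard brain-PET
image-quality metrics.

## Why

PET images reconstructed with OSEM get noisier with every iteration, and the
routine fix — stopping early and smoothing with a 3 mm Gaussian filter —
costs resolution and tissue contrast, especially at low injected dose. On
integrated PET/MR systems a perfectly co-registered T1-weighted image is
available for free, and its anatomy can regularize the reconstruction. This
package implements the Parallel Level Sets (PLS) approach: a penalized
maximum-likelihood reconstruction

$$\hat u = \arg\min_u \sum_i \bar y_i(u) - y_i \log \bar y_i(u)
\;+\; \beta \sum_x \sqrt{\alpha^2 + |\nabla u|^2 - (\nabla u \cdot \xi)^2},
\qquad \xi = \frac{\nabla v}{\sqrt{|\nabla v|^2 + \eta^2}},$$

optimized by one-step-late MAP-EM inside the usual ordered-subsets loop.
Image gradients parallel to MR gradients are exempt from penalization, so
edges shared by both modalities stay sharp while unmatched noise is smoothed
away; since $|\xi| < 1$, the prior can never *create* uptake where the PET
data show none. Intended users: researchers prototyping or benchmarking
anatomically guided PET reconstruction, and anyone needing a compact,
fully testable Poisson tomography sandbox in R.

## Worked example

Reconstruct a 12.5%-dose acquisition of the digital brain phantom with OSEM
(with and without the routine 3 mm post-filter) and with the MR-guided
algorithm at $\beta = 2$, and compare the phantom metrics at iteration 6:

```r
library(mrgpet)

ph    <- generate_brain_phantom(size = c(128, 128), spacing_mm = 1.2, seed = 1)
model <- system_model(c(128, 128), spacing_mm = 1.2, n_angles = 120)

sim  <- simulate_counts(ph$activity, model, total_counts = 2e6, seed = 1)
y125 <- thin_counts(sim$y, 0.125, seed = 2)      # emulate 12.5% dose

cfg      <- recon_config(n_subsets = 20, n_iterations = 6)
rec_osem <- osem(y125, model, cfg)
rec_mrg  <- mrg_reconstruct(y125, model, ph$prior, penalty_params(beta = 2), cfg)

meas <- place_tissue_rois(ph$rois)
rbind(OSEM        = phantom_metrics(rec_osem[[6]], meas),
      OSEM_GF_3mm = phantom_metrics(gaussian_postfilter(rec_osem[[6]], 3), meas),
      MRg_beta2   = phantom_metrics(rec_mrg[[6]], meas))
```

```
                  crc       cov    gm_wm    gm_csf      cnr
OSEM        0.9656209 1.5007175 3.896863 0.9398844 1.930318
OSEM_GF_3mm 0.9544641 0.4441245 3.863392 0.9385326 6.447274
MRg_beta2   1.0219131 0.5835591 4.065739 0.9566494 5.253520
```

Reading the numbers: `crc` is the contrast recovery coefficient
((GM/WM − 1)/3; 1 = the phantom's true 4:1 gray/white ratio fully
recovered), `cov` the white-matter coefficient of variation (relative
noise), `gm_wm`/`gm_csf` the tissue contrasts (truth: 4 and 1), `cnr` the
gray/white contrast-to-noise ratio. At one-eighth dose, unfiltered OSEM is
extremely noisy (COV 1.50); Gaussian filtering tames the noise but erodes
contrast (GM–WM 3.86, CRC 0.954); the MR-guided reconstruction cuts OSEM's
noise by ~61% while *exceeding* the filtered image's contrast on every
measure. The full dose × β × iteration sweep is one call:
`run_experiment(experiment_config())`.

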