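# gmrid — global filtering denoiser for 3D MRI

`gmrid` denoises 3D magnetic resonance volumes with a *global* filter:
every voxel is estimated as a similarity-weighted combination of **all**
voxels in the volume, not just a local search window. Patch-based methods
(NLM, BM3D, ...) trade estimation accuracy against the size of the search
neighborhood; the global formulation removes that compromise and is made
tractable by a low-rank Nyström approximation of the filter matrix, with
landmark voxels chosen by k-means clustering so that sampling concentrates
in informative tissue rather than the (large, homogeneous) background.

It is intended for researchers working with single-coil magnitude MR
volumes (NIfTI-1) who want a reproducible, parameter-light denoiser, and
for methods developers who want the individual stages — patch kernels,
landmark sampling, Nyström eigen-approximation, Sinkhorn scaling, spectral
shrinkage — exposed as composable, testable functions.

## Method

For a flattened noisy volume `y = x + n` (length `n`), a patch kernel
`M_ij = exp(-||p_i - p_j||^2 / (L h^2))` compares the `(2r+1)^3` patches
around voxels `i` and `j`. The row-normalized kernel defines the filter
`W`, approximated as a symmetric doubly stochastic matrix by Sinkhorn
scaling, so its eigenvalues satisfy `0 <= λ_n <= ... <= λ_1 = 1`. Denoising
is spectral shrinkage with iterative diffusion:

    x̂ = V_m E_m^k V_mᵀ y

where `V_m` holds the `m` leading eigenvectors and the eigenvalues are
raised to a diffusion exponent `k`. The pair `(k, m)` is selected by
exhaustively minimizing the risk proxy

    R(k, m) = Σ_{j<=m} ( (λ_j^{2k} - 2 λ_j^k) b_j^2 + σ² λ_j^{2k} ),

with `b_j^2` estimated from the data as `max((v_jᵀ y)² - σ², 0)`.

Forming `W` (size `n × n`) is impossible at MRI scale, so the eigensystem
is approximated from `l ≪ n` landmark voxels via the Nyström extension:
only the `l × l` landmark block `M1` and the `l × (n - l)` cross block
`M12` are ever computed, and the orthonormal filter eigenvectors come from
the one-shot eigendecomposition of
`O = W1 + W1^{-1/2} W12 W12ᵀ W1^{-1/2}`. Landmarks are the real voxels
nearest the `l` k-means centroids of the per-voxel patch features (a
uniform sampler is included as the baseline).

Rician magnitude noise is handled by a variance-stabilizing transform:
the volume is stabilized with `f(y) = sqrt(max(y² - σ², 0))`, filtered as
Gaussian, and mapped back with the bias-compensating inverse.

## Worked example

```r
library(gmrid)

ph    <- generate_phantom(c(32, 32, 32), n_tissues = 3, seed = 1)
noisy <- add_gaussian_noise(ph$truth, sigma_pct = 10, seed = 1)
res   <- denoise(noisy, noise_model("gaussian", 0.1), seed = 1)
res
#> <gmrid_denoise_result> gaussian noise (sigma = 0.1), kmeans sampling, l = 328, rank = 100
#>   selected k = 0, m = 99; sinkhorn residual 9.96e-07 (22 iters); 74.60 s

psnr(ph$truth, noisy, peak = 1);  psnr(ph$truth, res$volume, peak = 1)
#> [1] 19.96082
#> [1] 24.3163
ssim(ph$truth, noisy, peak = 1);  ssim(ph$truth, res$volume, peak = 1)
#> [1] 0.431938
#> [1] 0.9439257
```

The phantom is a piecewise-constant multi-tissue ellipsoid on a zero
background; at 10 % Gaussian noise the global filter recovers about
+4.4 dB of PSNR and lifts SSIM from 0.43 to 0.94. `res$k_hat`, `res$m_hat`
and `res$mse_curve` expose the selected diffusion/truncation parameters
and the full risk surface; `res$diagnostics` records the Sinkhorn
residual, landmark count and timing.

The same pipeline runs from the shell:

```sh
inst/cli/gmrid phantom --shape 32,32,32 --tissues 3 --noise rician \
    --sigma-pct 15 --seed 0 --out noisy.nii.gz --truth clean.nii.gz
inst/cli/gmrid denoise --input noisy.nii.gz --output denoised.nii.gz \
    --noise rician --sigma 0.15 --seed 0 --save-report report.json
inst/cli/gmrid sweep --rates 0.05,0.1,0.2 --rank 20 --seeds 10 --out sweep.csv
```

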