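---
title: "Global MRI denoising with a k-means Nyström filter: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global MRI denoising: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
establish about real data.

## The model

Denoising is posed as `y = x + n` on the flattened volume (length
`n = nx·ny·nz`). Each voxel is restored as a kernel-weighted average of
*every* voxel: the patch-similarity kernel
`M_ij = exp(-||p_i - p_j||² / (L h²))` (patches of `L = (2r+1)³` voxels),
row-normalized, defines the global filter `W`. We approximate `W` by a
symmetric doubly stochastic matrix via Sinkhorn scaling, which pins its
spectrum to `0 ≤ λ_n ≤ … ≤ λ_1 = 1` with a constant leading eigenvector.
Filtering is spectral shrinkage with iterative diffusion,
`x̂ = V_m E_m^k V_mᵀ y`: the truncation rank `m` discards weakly expressed
modes outright, and the diffusion exponent `k` attenuates the rest
smoothly (`λ^k`). Both are chosen by exhaustive minimization of the risk
proxy

```
R(k, m) = Σ_{j≤m} ( (λ_j^{2k} − 2 λ_j^k) b̂_j² + σ² λ_j^{2k} )
```

The clean spectral energies `b_j²` are unknown; since
`E[(v_jᵀ y)²] = b_j² + σ²` for orthonormal `v_j` under white noise, we use
`b̂_j² = max((v_jᵀ y)² − σ², 0)`. The constant `Σ x_i²` in the exact MSE
expansion is dropped — it cannot move the argmin.

The full `n × n` matrix is intractable, so the eigensystem comes from a
Nyström approximation: `l` landmark voxels give the blocks `M1` (`l × l`)
and `M12` (`l × (n−l)`), and the implied reconstruction is
`M̃ = A M1⁻¹ Aᵀ` with `A = [M1; M12ᵀ]`. Everything downstream touches only
these blocks; matrix-vector products with `M̃` cost `O(l·n)`.

### Why truncation happens after orthogonalization

Two inequivalent readings of "keep `r` eigenpairs" exist. Truncating the
landmark block `M1` to its top `r` eigenpairs *before* the Nyström
extension ties the retained subspace to the landmark distribution; for
deliberately non-uniform (k-means) landmarks this misaligns badly with the
full kernel's leading modes — in our experiments it made k-means sampling
look far *worse* than uniform, inverting the whole motivation for adaptive
sampling. The package therefore forms the complete rank-`l` reconstruction
and takes *its* `r` leading eigenpairs, obtained in one shot from
`O = W1 + W1^{-1/2} W12 W12ᵀ W1^{-1/2} = V_O E_O V_Oᵀ`, giving orthonormal
`Ṽ = [W1; W12ᵀ] W1^{-1/2} V_O E_O^{-1/2}` with `ṼᵀṼ = I` exactly by
construction. `nystrom_eigs()` still exposes the truncate-then-extend
variant because its algebra (extension rows `M12ᵀ γ1 ε1⁻¹`) is the
textbook identity the unit tests pin down.

### Sinkhorn on the sampled representation

The scaling runs entirely on the blocks: the symmetric fixed-point update
`d ← sqrt(d / (M̃ d))` needs only block matvecs, and applying the final
diagonal scaling to `M1` and `M12` scales the implied reconstruction
exactly (the scaling commutes with the Nyström formula). Stopping rule:
`max_i |row_sum_i − 1| ≤ 1e-6`, at most 200 sweeps, best iterate returned
with a warning flag on non-convergence. Tests verify all `n` reconstructed
row sums, and that a doubly stochastic input is a fixed point.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `patch_radius` | 1 | `3³` patches; the common 3D patch size in the NLM lineage |
| `bandwidth_h` | `max(σ, 0.05)` in `denoise()`; 0.4 in a bare `kernel_spec()` | kernel bandwidth per patch element, on `[0,1]` intensities |
| `rate` | 0.01 | landmark fraction `l/n`; `l = max(ceil(rate·n), rank)` |
| `rank` | 100 | retained eigenpairs, and the search space for `m` |
| `k_grid` | `{0, 0.5, …, 8}` | diffusion exponents searched |
| `sinkhorn_tol` / `max_iter` | `1e-6` / 200 | doubly-stochastic residual target |

Why these: the bandwidth follows the non-local-means convention
`h² = 2βσ²` per patch element with `β = ½` — a fixed bandwidth cannot
serve noise levels from 1 % to 15 % (far too diffuse at low noise, too
sharp at high), and normalizing the patch distance by `L` makes `h`
independent of the patch radius. The floor 0.05 keeps the kernel
non-degenerate on nearly clean data. A rank of 100 captures the bulk of
the spectral energy of piecewise-smooth volumes while keeping the
landmark eigen-decomposition trivial. Very small sampling rates only make
sense when `rate·n ≫ rank`; at the desk scales used here (16³–32³) the
default 0.01 keeps roughly three landmarks per retained eigenpair, which
is the same proportion a rate of 5·10⁻⁴ yields on a full-size
181×217×181 acquisition. `k_grid` includes 0 because pure truncation
(`λ⁰ = 1`) is a legitimate limit: with `σ → 0` the selected filter should
approach the identity, which requires the undamped spectrum.

Intensities are rescaled internally to `[0,1]` by the input volume's own
min/max and restored on output, so `σ` and `h` are quoted on that range
("10 % noise" means `σ = 0.1`). The per-volume maximum (rather than a
modality-nominal maximum) is a documented convention, not a claim about
how acquisition scales should be normalized.

## Rician noise and the VST

Magnitude MR data carries Rician noise `y = sqrt((x+n₁)² + n₂²)`, whose
variance depends on the signal. The pipeline stabilizes with the closed
form `f(y) = sqrt(max(y² − σ², 0))`, filters as if Gaussian with level
`σ`, and inverts with `f⁻¹(d) = sqrt(d² + σ²)` above the round-trip
threshold `2σ`, continued linearly through the origin below it so that
fully smoothed background maps toward 0 rather than acquiring the
`σ` Rayleigh floor. Monte-Carlo checks show the stabilized standard
deviation stays within ±13 % of `σ` over SNR 1–10 (the contract allows
15 %). Two properties cannot hold simultaneously: an inverse that
round-trips exactly (`f⁻¹(f(y)) = y`) and one that is exactly unbiased
for the *mean* of stabilized draws at low SNR — the residual Rician bias
after the exact inverse is `≈ σ²/(2x)`, i.e. under 2 % only for
`x ≥ 5σ`. The package keeps the exact round trip (so clean signals pass
through unchanged) and documents the low-SNR bias; the linear low-end
continuation recovers most of the background bias in practice.

## The synthetic phantom

`generate_phantom()` emulates the regime the method targets: an
ellipsoidal multi-tissue object occupying ~23 % of the volume on an
*exact-zero* background (the dominance of background voxels is precisely
what makes adaptive landmark sampling worthwhile), with tissue regions cut
from a smooth random field so boundaries are geometrically smooth but
intensities are exactly piecewise constant. Defaults: 16³ voxels, 3
tissues with means evenly spaced in `[0.35, 1]`, field smoothness 3
cycles/extent, deterministic per seed. Noise is added at a stated
percentage of the maximum intensity, Gaussian or Rician, matching the
1–15 % range conventionally studied.

What it does *not* emulate: anatomical texture, partial-volume ramps,
field inhomogeneity, spatially varying noise, multi-coil (non-central
chi) statistics. Consequently the tests establish the algebraic
correctness of the pipeline and its behavior under the stated noise
models — not clinical image quality. PSNR/SSIM improvements on the
phantom should be read as directional evidence only; absolute values on
real acquisitions will differ.

## Problem sizes and numerical choices

Tests and the acceptance script run at 12³–32³: dense-oracle comparisons
need the explicit `n × n` kernel, and 12³ (n = 1728) keeps a full
eigendecomposition cheap while 32³ exercises the sampled path at a
realistic landmark-to-voxel ratio. The sampling-accuracy sweep uses the
16³ default phantom with 5 % Gaussian noise, rank 20, ten seeds — chosen
once as mid-range, and because the dense reference kernel (n = 4096) and
its exact truncation are computed exactly there.

Numerical guards, all logged when they fire: `M1` gets a relative ridge
`1e-10·λ_max` before inversion when its spectrum underflows (duplicate
patches make it numerically semidefinite); `W1^{-1/2}` clips eigenvalues
at the same relative floor; filter eigenvalues marginally above 1 from
approximation error are clipped to 1 (a `λ > 1` would amplify noise under
`λ^k`); non-positive directions of `O` are dropped. Selection ties break
toward smaller `k`, then smaller `m` (the weakest filter among equals).
Empty k-means clusters are re-seeded from the maximin-farthest voxel;
on degenerate (duplicate-heavy) feature sets where Lloyd iteration cannot
run, the k-means++ seeding itself serves as the landmark set. Constant
volumes rescale to all-zeros and pass through unharmed.

## Known limitations

- The canonical linearization is R's native array order (1-based, first
  axis fastest); all index arithmetic goes through `vol_index()` /
  `vol_coords()`.
- σ is always user-supplied; no noise estimation is performed.
- Only the Gaussian-of-patch-distance (NLM) kernel is implemented; the
  kernel family field is a registry point for transform-domain kernels.
- `relative_accuracy()` and `reconstruct_kernel()` materialize dense
  matrices and are test/analysis tools, capped at `dense_limit` rows.
- 4D series, DICOM, and complex multi-coil data are out of scope.
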