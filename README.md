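# pcgenergy

Quantifying non-repeating events in heart-sound recordings.

## The problem

A phonocardiogram (PCG) is dominated by the repeating sounds of the beating
heart itself — S1 at the start of systole, S2 at the start of diastole. The
clinically interesting part is often what does *not* repeat from beat to
beat: the high-frequency pressure transients of cavitation near a mechanical
heart valve, murmurs, or other intermittent events. `pcgenergy` implements
an energy-decomposition pipeline that separates the two.

With `HB` segmented, truncated, superimposed heart beats `p[m, n]`
(`m` = beat, `n` = sample, `N` samples per beat):

- ensemble average: `p_ea[n] = (1/HB) * Σ_m p[m, n]`
- deterministic energy: `E_det = (1/N) * Σ_k |F(p_ea)[k]|²` — the energy of
  the repeating, beat-locked component (by Parseval this equals
  `Σ_n p_ea[n]²`)
- total energy: `E_total = (1/HB) * Σ_m (1/N) * Σ_k |F(p[m,·])[k]|²` — the
  mean per-beat energy
- non-deterministic energy: `E_nondet = E_total − E_det ≥ 0`, reported as
  `100 · E_nondet / E_total` percent.

Algebraically `E_nondet = (1/HB²) Σ_{i<j} Σ_n (p[i,n] − p[j,n])²`: only
*differences* between beats contribute, so anything that repeats perfectly
cancels, and for identical superimposed beats `E_nondet = 0`.

Because any residual misalignment between beats also shows up as
"difference", the pipeline aligns beats on their S1 (or S2) peaks after the
initial segmentation, and can drop beats whose required shift is so large
that they are better treated as segmentation failures. A Short-Time Fourier
Transform extension resolves the same decomposition over time within the
beat, localizing where in the cardiac cycle the non-deterministic energy
lives.

See `vignette("energy-decomposition")` for the model, assumptions,
parameter choices and validation strategy.

## Worked example

Generate a synthetic 44.1 kHz recording of 10 beats with a cavitation-like
burst injected into beats 2, 5 and 8, then run the full pipeline:

```r
library(pcgenergy)

spec <- pcg_fixture_spec(hb_count = 10, seed = 42,
                         injected_component = list(
                           waveform = cavitation_burst(2000, 8000, 44100, 0.3),
                           beats = c(2, 5, 8), offset_time = 0.55))
g <- generate_synthetic_pcg(spec)
write_wav(normalize_signal(g$signal), "fixture.wav")

res <- run_analysis("fixture.wav",
                    analysis_config(alignment_mode = "best", stft = TRUE))
print(res)
```

```
<pcg_analysis> fixture.wav: 10 beats segmented, 10 used
<energy_summary> (FT, alignment: S1, 10 beats x 39734 samples)
  E_det    = 412.097
  E_total  = 426.038
  E_nondet = 13.9406
  non-deterministic energy: 3.27% of total
<alignment_report> S1 alignment, 10 beats (reference beat 1)
  mean |shift| 106.50, sd |shift| 70.75, sd shift 131.86 samples
  STFT-route non-deterministic energy: 3.19%
```

Reading this: the internal Shannon-energy detector found all 10 beats; S1
alignment was selected (`"best"` runs both S1 and S2 alignment and keeps
the lower percentage); after aligning, 3.27% of the signal energy does not
repeat beat-to-beat — that is the injected bursts plus the generator's
noise floor. The STFT route, summed over frames, agrees (3.19%). Running
the same file with `alignment_mode = "none"` reports 61.98%: without peak
alignment, the segmentation's timing errors masquerade as a large
non-repeating component, which is exactly the failure mode the alignment
stage exists to remove.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/pcgenergy.R analyze --input fixture.wav --align best --out report.json
```

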