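# Example atlaseval run configuration.
# All randomness in a run derives from `seed`; re-running a config
# reproduces its outputs byte for byte.
seed: 9
outdir: atlaseval-out

cohort:
  n: 8                     # cases in the synthetic library
  n_test: 2                # cases held out as test cases
  p_incline15: 0.5         # proportion scanned on a 15 degree board
  p_large: 0.5             # proportion with large chest-wall separation
  separation_cut_cm: 19    # small/large class boundary (cm)
  grid:                    # coarse grid for a fast demonstration run;
    dim: [48, 48, 48]      # drop this block for the 96^3 default
    spacing_mm: [5, 5, 5]
    origin_cm: [0, -12, -16]

groups:
  - {label: het4, size: 4}          # heterogeneous / mixed atlases
  - {label: deg15, size: 3, incline: 15}   # character-specific: 15 degrees
  # add `match: MTC` (or NMTC) to force test cases to match (violate)
  # the group filters; needs enough matching test-role cases

mas:
  mode: pseudo             # "pseudo": perturb references (known truth);
                           # "mas": full registration + fusion pipeline
  perturbation:
    translation_cm: [0.5, 0, 0]
    scale: [1, 1, 1]
    boundary_noise_sd_cm: 0.2
  policy:
    vote_fraction: 0.5

metrics:
  centre_mode: own         # "own" or "reference"
  decimals: 1              # reporting precision (cm)

rules:
  threshold_cm: 0.3        # clinical-relevance magnitude cut
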