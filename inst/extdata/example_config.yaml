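# Example configuration for the detwin command-line tool.
# A hexagonal P6_3-type crystal with the standard two-mode twin ambiguity.
seed: 1
cell: [100, 100, 58.8, 90, 90, 120]
symmetry:
  point_group: "6"
  friedel: true
  # ambiguity_operators:      # row-major 3x3 integer matrices; default is
  #   - [1,0,0, 0,1,0, 0,0,1] # identity plus the hexagonal twin law
  #   - [0,1,0, 1,0,0, 0,0,-1]
simulate:
  n_patterns: 500
  reflections_per_pattern: 100
  d_min: 3
  intensity_scale: 1000
  partiality_model: uniform   # or resolution_dependent
  p_floor: 0.1
  noise: poisson              # or none
em:
  max_iterations: 20
  min_common: 5
  low_res_cutoff_d: 20
  convergence_fraction: 0.001
evaluate:
  shell: [3, 5]
paths:
  dataset: detwin_out/dataset.txt
  model: detwin_out/model.txt
  reference: detwin_out/true_model.txt
  assignments: detwin_out/assignments.tsv
  truth_modes: detwin_out/truth_modes.tsv
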