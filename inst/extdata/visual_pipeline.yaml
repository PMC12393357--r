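# Example pipeline configuration: synthetic 3-minute light ON/OFF/ON assay.
# Run with:  Rscript inst/cli/calmov.R run inst/extdata/visual_pipeline.yaml
seed: 7
input:
  preset: visual
  n_cells: 12
  field: [96, 96]
register:
  reference_frame: 1
  max_shift: 6
segment:
  projection: sum
  rolling_ball_radius: 20
  threshold: otsu
  min_area: 8
  max_area: 300
dff:
  baseline_start: 1
  baseline_end: 60
smooth:
  sigma: 1
detect:
  lag: 30
  threshold: 3
  influence: 0.5
classify:
  criteria:
    mode: consecutive
    k: 3
    direction: increase
  off_label: "OFF"
  on_label: "ON2"
export:
  prefix: fish01
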