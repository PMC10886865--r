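# Example configuration for the keratofem CLI pipeline.
# Run from a working directory of your choice:
#   keratofem fixture --config run.yaml
#   keratofem mesh    --config run.yaml
#   keratofem solve   --config run.yaml
#   keratofem sfg     --config run.yaml --method displacements
#   keratofem sfg     --config run.yaml --method prestress
#   keratofem compare --config run.yaml
#   keratofem report  --config run.yaml
out_dir: out
global:
  log_level: info
fixture:
  grade: G1            # none | G1 | G2 | G3 | G4
mesh:
  n_layers: 4
  n_angular: 2
  n_transition: 1
solve:
  iop_mmhg: 15
  bc: embedded         # embedded | pivoting
sfg:
  iop_mmhg: 15
  bc: embedded
  tol: 1.0e-9
compare:
  label: G1
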