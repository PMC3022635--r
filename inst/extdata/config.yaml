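# Example run configuration for the potaccess command-line pipeline.
seed: 1
inputs:
  municipalities: municipalities.csv
  facilities: facilities.csv
  flows: flows.csv
  trips: trips.csv
facility_type: bakeries
impedance:
  preset: bakeries
grid:
  resolution: 500
  margin: 2000
commuter:
  theta: 1
  max_d: 65000
outputs:
  dir: output
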