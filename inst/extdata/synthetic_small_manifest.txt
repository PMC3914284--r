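# Manifest for the synthetic miniature fixture pair (fixtureSmall)
imaging_samples: 30
imaging_controls: 24
imaging_cases: 6
imaging_features: 6
imaging_informative: img0001,img0002
molecular_samples: 12
molecular_controls: 8
molecular_cases: 4
molecular_features: 40
molecular_informative: gene0001,gene0002,gene0003
seed: 42
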