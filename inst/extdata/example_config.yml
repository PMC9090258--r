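# Example simulation/run configuration (synthetic specimen).
# Densities are cells/um^2 per region class and phenotype.
window_width: 600
window_height: 400
seed: 7
noise_sd: 0.2
gates:
  CD3:    {intensity: 10, coverage: 0.3}
  CD68:   {intensity: 10, coverage: 0.3}
  CD11c:  {intensity: 10, coverage: 0.3}
  CD163:  {intensity: 10, coverage: 0.3}
  pSTAT3: {intensity: 10, coverage: 0.3}
densities:
  edge:     {CD3: 6.0e-4, CD68: 4.0e-4, CD163: 9.0e-4, negative: 2.0e-3}
  tumor:    {CD3: 6.0e-4, CD68: 8.0e-4, CD163: 7.0e-4, negative: 2.5e-3}
  necrosis: {CD3: 1.2e-4, CD68: 1.5e-4, CD163: 3.0e-4, negative: 8.0e-4}
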