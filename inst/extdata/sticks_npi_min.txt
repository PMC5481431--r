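# state: npi_min  (synthetic stand-in stick lines, npi* state at its minimum)
# energy_eV oscillator_strength
526.4000 1.000
529.6000 0.300
531.3000 0.850
533.6000 0.450
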