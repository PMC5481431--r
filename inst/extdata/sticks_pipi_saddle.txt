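# state: pipi_saddle  (synthetic stand-in stick lines, pipi* state at the saddle point)
# energy_eV oscillator_strength
526.3000 0.025
531.1000 0.480
533.2000 0.300
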