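# state: pipi_FC  (synthetic stand-in stick lines, pipi* state at Franck-Condon geometry)
# energy_eV oscillator_strength
526.4000 0.025
530.9000 0.500
533.0000 0.300
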