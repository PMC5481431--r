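# state: GS  (synthetic stand-in stick lines, oxygen K-edge thymine ground state)
# energy_eV oscillator_strength
531.3837 1.000
532.2210 0.900
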