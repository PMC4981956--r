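taxon,first_occurrence,last_occurrence
Anguillavus,99,98
Luenchelys,95,93.9
Urenchelys,95,93.9
Anguilloides,49,48
Anguilla_ignota,47.8,47.8
Anguilla_elegans,13,13
Anguilla_rostrata,0,0
Bolcyrus,49,48
Voltaconger,49,48
Conger_myriaster,0,0
Paranguilla,49,48
Gymnothorax_moringa,0,0
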