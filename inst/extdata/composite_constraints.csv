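mrca_of,age,kind
Anguillavus;Gymnothorax_moringa,116,fixed
Anguilloides;Gymnothorax_moringa,99,fixed
Anguilloides;Anguilla_rostrata,81,fixed
Anguilla_ignota;Anguilla_rostrata,60,fixed
Bolcyrus;Conger_myriaster,86,fixed
Paranguilla;Gymnothorax_moringa,76,fixed
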