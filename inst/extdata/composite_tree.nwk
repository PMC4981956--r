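(Anguillavus,((Luenchelys,Urenchelys)C,((Anguilloides,(Anguilla_ignota,Anguilla_elegans,Anguilla_rostrata)G)F,((Bolcyrus,Voltaconger,Conger_myriaster)I,(Paranguilla,Gymnothorax_moringa)K)H)E)B)A;
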