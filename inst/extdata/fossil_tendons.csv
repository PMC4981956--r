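taxon_id,element,side,k_min,k_max,tl_start,tl_end,element_length
Luenchelys,ENB,epaxial,1,1,,,
Anguilloides,ENB,epaxial,2,2,,,
Anguilla_elegans,ENB,epaxial,1,2,,,
Bolcyrus,ENB,epaxial,2,2,89,97,
Bolcyrus,EPB,hypaxial,1,2,,,
Voltaconger,ENB,epaxial,2,2,89,97,
Voltaconger,EPB,hypaxial,1,2,,,
Paranguilla,ENB,epaxial,2.5,2.5,,,
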