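molecule_id,kind,state_from,state_to,wavelength_nm,oscillator_strength,method
BIMC,emission,1,0,458.2,1.2263,STEOM-DLPNO-CCSD
BIMC,emission_experimental,1,0,454.0,,experiment
BIMC-Protonated,emission,1,0,512.9,1.1905,STEOM-DLPNO-CCSD
BIMC-Protonated,emission_experimental,1,0,514.0,,experiment
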