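molecule_id,kind,state_from,state_to,wavelength_nm,oscillator_strength,method
BIMC,absorption,0,1,378.5,1.4086,TDDFT/PBE0
BIMC,absorption,0,2,330.2,0.0559,TDDFT/PBE0
BIMC,emission,1,0,484.7,1.8387,TDDFT/PBE0
BIMC,emission_experimental,1,0,454.0,,experiment
BIMC-Protonated,absorption,0,1,419.0,1.1910,TDDFT/PBE0
BIMC-Protonated,absorption,0,2,360.2,0.2391,TDDFT/PBE0
BIMC-Protonated,emission,1,0,499.7,1.7713,TDDFT/PBE0
BIMC-Protonated,emission_experimental,1,0,514.0,,experiment
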