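molecule_id,kind,state_from,state_to,wavelength_nm,oscillator_strength,method
BBP,absorption,0,1,320.6,0.8519,TDDFT/PBE0
BBP,absorption,0,2,303.4,0.2940,TDDFT/PBE0
BBP,absorption,0,3,290.0,0.3044,TDDFT/PBE0
BBP,emission,1,0,369.1,1.2774,TDDFT/PBE0
BBP,emission_experimental,1,0,385.0,,experiment
BBP-Protonated,absorption,0,1,324.5,0.8417,TDDFT/PBE0
BBP-Protonated,absorption,0,2,302.9,0.3461,TDDFT/PBE0
BBP-Protonated,emission,1,0,372.3,1.1886,TDDFT/PBE0
BBP-Protonated,emission_experimental,1,0,396.0,,experiment
BBP-Deprotonated,absorption,0,1,328.9,0.8545,TDDFT/PBE0
BBP-Deprotonated,absorption,0,2,315.0,0.1571,TDDFT/PBE0
BBP-Deprotonated,emission,1,0,381.6,1.2980,TDDFT/PBE0
BBP-Deprotonated,emission_experimental,1,0,410.0,,experiment
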