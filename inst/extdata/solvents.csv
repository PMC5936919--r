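name,molar_mass_g_mol,viscosity_mPa_s,density_kg_m3,vapour_pressure_hPa,toxicity_class,association_factor,miscible_with_water
n-butanol,72.1,3.10,808,18.3,3,1.0,TRUE
n-octanol,130.2,7.40,827,8.7,3,1.0,TRUE
ethyl acetate,88.1,0.43,894,97,3,1.0,FALSE
n-hexane,86.2,0.29,655,160,2,1.0,FALSE
n-heptane,100.2,0.39,684,48,3,1.0,FALSE
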