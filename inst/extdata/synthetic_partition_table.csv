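# Synthetic partition-coefficient table (representative stand-in; the
# published per-solvent bar values are not machine-readable). logP_pred
# emulates solvation-model output, logP_exp shake-flask triplicate means.
solute,solvent,medium,logP_pred,logP_exp
(S)-(+)-carvone,n-heptane,water,2.778,2.74
(S)-(+)-carvone,n-hexane,water,2.80,2.85
(S)-(+)-carvone,ethyl acetate,water,2.90,2.95
(S)-(+)-carvone,n-butanol,water,1.90,0.20
(S)-(+)-carvone,n-octanol,water,2.50,2.42
(S)-(+)-carvone,n-heptane,salt medium,2.90,2.84
(S)-(+)-carvone,n-hexane,salt medium,2.92,2.96
(S)-(+)-carvone,ethyl acetate,salt medium,3.00,3.05
(S)-(+)-carvone,n-octanol,salt medium,2.55,1.60
terpinen-4-ol,n-heptane,water,3.30,2.70
terpinen-4-ol,n-hexane,water,3.20,2.65
terpinen-4-ol,ethyl acetate,water,3.00,2.80
terpinen-4-ol,n-butanol,water,2.00,0.30
terpinen-4-ol,n-octanol,water,3.10,2.20
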