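# Three-fibre PTFE hollow-fibre contactor (small-scale, glass housing).
# Printed specifications: 3 fibres, 1 um nominal pores, 3 mm ID, 20 cm
# length, 56 cm2 total inner area; lumen flow 3 ml/min, shell flow
# 40 ml/min, aqueous:organic phase ratio 2:1, 25 degC.
#
# SYNTHETIC PLACEHOLDERS: the wall/shell parameters below are not printed
# for this module and are documented assumptions (see package vignette):
# d_o_mm, porosity, tortuosity, shell_id_mm, and the reservoir volumes
# v_w_ml/v_s_ml (only their 2:1 ratio is specified).

n_fibres = 3
d_i_mm = 3
d_o_mm = 3.3
length_cm = 20
pore_um = 1
porosity = 0.5
tortuosity = 2
shell_id_mm = 10
beta = 5.8

mode = in-out
flow_lumen_ml_min = 3
flow_shell_ml_min = 40
temperature_c = 25
v_w_ml = 100
v_s_ml = 50
c_w0_mg_ml = 0.15
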