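system,delta_h_kJ_mol,delta_s_J_molK,dg_298_kJ_mol,dg_303_kJ_mol,dg_310_kJ_mol
AML,6.99,100.32,-22.90,-23.40,-24.10
ATN,25.94,159.06,-21.46,-22.25,-23.37
FUR,380.01,1310.00,-10.38,-16.93,-26.10
QUI,15.08,131.36,-24.07,-24.72,-25.64
VAL,100.10,393.25,-17.08,-19.05,-21.80
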