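state,temperature_K,dg_kcal_mol,sd_kcal_mol
I,298,-8.827,0.062
II,298,-6.653,0.115
III,298,-21.166,0.124
I,333,-6.249,0.051
II,333,-6.473,0.051
III,333,-17.164,0.074
IV,333,-2.548,0.038
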