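# Computed molar reaction free energies (eV) of the Me2-crocetin oxidation
# network: H-abstraction by OH., radical dimerization, disproportionation
# (primary open/closed-shell species and cyclic products) and radical-parent
# complexation. R.Ca / R.Cb denote the radicals after H-abstraction from the
# Ca / Cb methyl groups; primary disproportionation products are labelled by
# the two oxidized carbons and their electronic state (1A singlet, 3a
# triplet); lower bounds are stored as their bound value.
label	reactants	products	delta_g_ev
oxidation_Ca	Me2-crocetin + OH.	R.Ca + H2O	-1.98
oxidation_Cb	Me2-crocetin + OH.	R.Cb + H2O	-1.94
dimer_CaCa	R.Ca + R.Ca	dimer CaCa	-1.09
dimer_CaCb	R.Ca + R.Cb	dimer CaCb	-1.05
dimer_CbCb	R.Cb + R.Cb	dimer CbCb	-1.12
disp_CaCa_to_CaCap_1A	R.Ca + R.Ca	Me2-crocetin(-2H) CaCap 1A + Me2-crocetin	-0.26
disp_CaCa_to_CaCap_cyclic	R.Ca + R.Ca	Me2-crocetin(-2H) CaCap cyclic + Me2-crocetin	-0.48
disp_CaCa_to_CaCb_3a	R.Ca + R.Ca	Me2-crocetin(-2H) Ca.Cb. 3a + Me2-crocetin	0.30
disp_CaCa_to_CaCb_1A	R.Ca + R.Ca	Me2-crocetin(-2H) Ca.Cb. 1A + Me2-crocetin	0.30
disp_CaCa_to_CaCb_cyclic	R.Ca + R.Ca	Me2-crocetin(-2H) CaCb cyclic + Me2-crocetin	-1.28
disp_CaCa_to_CaCbp_1A	R.Ca + R.Ca	Me2-crocetin(-2H) CaCbp 1A + Me2-crocetin	-0.26
disp_CaCa_to_CaCbp_cyclic	R.Ca + R.Ca	Me2-crocetin(-2H) CaCbp cyclic + Me2-crocetin	-0.39
disp_CaCb_to_CaCap_1A	R.Ca + R.Cb	Me2-crocetin(-2H) CaCap 1A + Me2-crocetin	-0.30
disp_CaCb_to_CaCap_cyclic	R.Ca + R.Cb	Me2-crocetin(-2H) CaCap cyclic + Me2-crocetin	-0.52
disp_CaCb_to_CaCb_3a	R.Ca + R.Cb	Me2-crocetin(-2H) Ca.Cb. 3a + Me2-crocetin	0.26
disp_CaCb_to_CaCb_1A	R.Ca + R.Cb	Me2-crocetin(-2H) Ca.Cb. 1A + Me2-crocetin	0.26
disp_CaCb_to_CaCb_cyclic	R.Ca + R.Cb	Me2-crocetin(-2H) CaCb cyclic + Me2-crocetin	-1.32
disp_CaCb_to_CaCbp_1A	R.Ca + R.Cb	Me2-crocetin(-2H) CaCbp 1A + Me2-crocetin	-0.30
disp_CaCb_to_CaCbp_cyclic	R.Ca + R.Cb	Me2-crocetin(-2H) CaCbp cyclic + Me2-crocetin	-0.43
disp_CaCb_to_CbCbp_1A	R.Ca + R.Cb	Me2-crocetin(-2H) CbCbp 1A + Me2-crocetin	-0.29
disp_CaCb_to_CbCbp_cyclic	R.Ca + R.Cb	Me2-crocetin(-2H) CbCbp cyclic + Me2-crocetin	-1.04
disp_CbCb_to_CaCb_3a	R.Cb + R.Cb	Me2-crocetin(-2H) Ca.Cb. 3a + Me2-crocetin	0.22
disp_CbCb_to_CaCb_1A	R.Cb + R.Cb	Me2-crocetin(-2H) Ca.Cb. 1A + Me2-crocetin	0.22
disp_CbCb_to_CaCb_cyclic	R.Cb + R.Cb	Me2-crocetin(-2H) CaCb cyclic + Me2-crocetin	-1.36
disp_CbCb_to_CaCbp_1A	R.Cb + R.Cb	Me2-crocetin(-2H) CaCbp 1A + Me2-crocetin	-0.33
disp_CbCb_to_CaCbp_cyclic	R.Cb + R.Cb	Me2-crocetin(-2H) CaCbp cyclic + Me2-crocetin	-0.47
disp_CbCb_to_CbCbp_1A	R.Cb + R.Cb	Me2-crocetin(-2H) CbCbp 1A + Me2-crocetin	-0.33
disp_CbCb_to_CbCbp_cyclic	R.Cb + R.Cb	Me2-crocetin(-2H) CbCbp cyclic + Me2-crocetin	-1.08
complex_Ca	R.Ca + Me2-crocetin	(R.Ca, Me2-crocetin)	-0.52
complex_Cb	R.Cb + Me2-crocetin	(R.Cb, Me2-crocetin)	-0.52
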