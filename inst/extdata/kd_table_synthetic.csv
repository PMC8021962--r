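# Homophilic dissociation constants for the cadherin panel.
# Only the Cdh2 entry is anchored to a measured value (analytical
# ultracentrifugation, 25.8 uM). Every row tagged 'synthetic:' is a
# placeholder on the plausible low-micromolar scale of classical-cadherin
# EC1 trans-dimerization, shipped solely so the pipeline runs end to end;
# replace with curated affinities for real analyses.
cadherin,kd_molar,cadherin_type,specificity_group,source
Cdh1,96.5e-6,type I,none,synthetic:typeI_scale_placeholder
Cdh2,25.8e-6,type I,none,Katsamba2009_AUC
Cdh3,45e-6,type I,none,synthetic:typeI_scale_placeholder
Cdh4,60e-6,type I,none,synthetic:typeI_scale_placeholder
Cdh6,5e-6,type II,A,synthetic:typeII_scale_placeholder
Cdh9,10e-6,type II,A,synthetic:typeII_scale_placeholder
Cdh10,8e-6,type II,A,synthetic:typeII_scale_placeholder
Cdh7,15e-6,type II,B,synthetic:typeII_scale_placeholder
Cdh12,12e-6,type II,B,synthetic:typeII_scale_placeholder
Cdh18,20e-6,type II,B,synthetic:typeII_scale_placeholder
Cdh20,18e-6,type II,B,synthetic:typeII_scale_placeholder
Cdh8,3e-6,type II,C,synthetic:typeII_scale_placeholder
Cdh11,2e-6,type II,C,synthetic:typeII_scale_placeholder
Cdh24,6e-6,type II,C,synthetic:typeII_scale_placeholder
Cdh13,50e-6,atypical,none,synthetic:atypical_scale_placeholder
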