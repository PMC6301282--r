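id	name	compartment	printed_name
hdacp_c	(3R)-3-hydroxydecanoyl-ACP	c	(3R)-3-Hydroxydecanoyl-acyl-carrier protein
coa_c	coenzyme A	c	Coenzyme A
hdcoa_c	(S)-3-hydroxydecanoyl-CoA	c	(S)-3-Hydroxydecanoyl-CoA
acp_c	acyl carrier protein	c	acyl carrier protein
haa_c	3-hydroxydecanoyl-3-hydroxydecanoate	c	3-hydroxydecanoyl-3-hydroxydecanoate
dtdpddm_c	dTDP-4-dehydro-6-deoxy-L-mannose	c	dTDP-4-dehydro-6-deoxy-L-mannose
h_c	proton	c	H+
dtdp_c	dTDP	c	dTDP
rhl_c	mono-rhamnolipid	c	L-rhamnosyl-3-hydroxydecanoyl-3-hydroxydecanoate
rhl2_c	di-rhamnolipid	c	L-rhamnosyl-L-rhamnosyl-3-hydroxydecanoyl-3-hydroxydecanoate
bhbhcoa_c	beta-hydroxydecanoyl-beta-hydroxydecanoyl-S-CoA	c	beta-hydroxydecanoyl-beta-hydroxydecanoyl-S-CoA
h2o_c	water	c	H2O
rhl_e	mono-rhamnolipid	e	extracellular mono-rhamnolipid
rhl2_e	di-rhamnolipid	e	extracellular di-rhamnolipid
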