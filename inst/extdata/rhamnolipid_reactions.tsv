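code	formula	reversibility	role	gpr
RHLA	hdacp_c + coa_c --> hdcoa_c + acp_c	irreversible	core	rhlA
RHLB	haa_c + dtdpddm_c + h_c --> dtdp_c + rhl_c	irreversible	core	rhlB
RHLC	dtdpddm_c + h_c + rhl_c --> dtdp_c + rhl2_c	irreversible	core	rhlC
3H3H	2 bhbhcoa_c + h2o_c --> haa_c + coa_c	irreversible	core	phaC1
PHAC	hdcoa_c --> 2 bhbhcoa_c + coa_c	irreversible	core	phaC2
RHLt	rhl_c --> rhl_e	irreversible	transport	NA
EX_rhl	rhl_e -->	irreversible	exchange	NA
RHL2t	rhl2_c --> rhl2_e	irreversible	transport_di	NA
EX_rhl2	rhl2_e -->	irreversible	exchange_di	NA
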