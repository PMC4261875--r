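virus_tip	host_tip
ChrEFV	golden_mole
SloEFV	sloth
RhiFV	horseshoe_bat
PSFVaye	aye_aye
FFV	cat
EFV	horse
BFV	cow
PSFVgal	galago
PFV	human
SFVcpz	chimpanzee
SFVgor	gorilla
SFVora	orangutan
SFVmac	macaque
SFVagm	african_green_monkey
SFVspm	spider_monkey
SFVsqu	squirrel_monkey
SFVmar	marmoset
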