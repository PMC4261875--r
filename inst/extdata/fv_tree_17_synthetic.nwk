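(ChrEFV:0.92,(SloEFV:0.74,(((RhiFV:0.59,PSFVaye:0.61):0.0564,(FFV:0.57,(EFV:0.55,BFV:0.95):0.015):0.022):0.11,(PSFVgal:0.54,(((SFVora:0.12,(SFVgor:0.066,(PFV:0.047,SFVcpz:0.048):0.018):0.051):0.095,(SFVmac:0.10,SFVagm:0.10):0.11):0.10,((SFVspm:0.17,SFVsqu:0.15):0.05,SFVmar:0.18):0.14):0.23):0.16):0.037):0.028);
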