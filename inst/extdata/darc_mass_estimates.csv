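construct,method,value,rg_nm,dmax_nm
dArc1-NL,saxs_envelope,19.6,,
dArc1-NL,saxs_bayesian,18.7,,
dArc1-NL,mals,24,,
dArc1-NL,monomer_sequence,8.2,2.0,7.4
dArc2-NL,saxs_envelope,34.0,,
dArc2-NL,saxs_bayesian,31.7,,
dArc2-NL,mals,37,,
dArc2-NL,monomer_sequence,8.4,2.4,7.8
dArc1-CL,saxs_envelope,17.6,,
dArc1-CL,saxs_bayesian,17.4,,
dArc1-CL,mals,22,,
dArc1-CL,monomer_sequence,11,2.0,7.1
dArc2-CL,saxs_envelope,16.2,,
dArc2-CL,saxs_bayesian,19.9,,
dArc2-CL,mals,23,,
dArc2-CL,monomer_sequence,10,2.0,7.9
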