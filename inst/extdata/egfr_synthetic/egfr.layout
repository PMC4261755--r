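#cmapkit-layout v1
Grb2	300	210
Shc	160	290
Sos	440	250
egf	40	60
egfr	160	130
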