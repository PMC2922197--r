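peptide	ec
NSISISGYH	5.4.99.2
ISISGYHMQEAG	5.4.99.2
MKWVTFISLLH	1.1.1
DAHKSEVAHRF	1.1.1
KDLGEENFKAL	2.7.7
VLIAFAQYLQQ	2.7.7
CPFEDHVKLVN	3.6.1
ELTEFAKTCVA	3.6.1
DESHAGCEKSL	6.1.1.1
HTLFGDKLCTV	6.1.1.4
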