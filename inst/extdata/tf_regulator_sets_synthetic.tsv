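mirna	regulator
miR-15a	Batf
miR-15a	Bcl11b
miR-15a	Brd4
miR-15a	Btaf1
miR-15a	Cbfb
miR-15a	Cebpa
miR-15a	Cebpb
miR-15a	Ctcf
miR-15a	DECOY_MIR15A_01
miR-15a	DECOY_MIR15A_02
miR-15a	DECOY_MIR15A_03
miR-15a	DECOY_MIR15A_04
miR-15a	DECOY_MIR15A_05
miR-15a	Ep300
miR-15a	Erg
miR-15a	Ets1
miR-15a	Hdac2
miR-15a	Ikzf1
miR-15a	Mafb
miR-15a	Max
miR-15a	Med1
miR-15a	Myc
miR-15a	Nelfe
miR-15a	Nr1d1
miR-15a	Nr3c1
miR-15a	Otx2
miR-15a	Pou5f1
miR-15a	Pparg
miR-15a	Rad21
miR-15a	Rela
miR-15a	Smarca4
miR-15a	Spi1
miR-15a	Suz12
miR-15a	Tcf12
miR-15a	Tfap4
miR-15a	Zfp281
miR-15a	Zfp384
let-7d	Cebpa
let-7d	DECOY_LET7D_01
let-7d	DECOY_LET7D_02
let-7d	DECOY_LET7D_03
let-7d	DECOY_LET7D_04
let-7d	DECOY_LET7D_05
let-7d	Spi1
miR-497a	Bcl11b
miR-497a	Brd4
miR-497a	Cbfb
miR-497a	Cebpb
miR-497a	Ctcf
miR-497a	DECOY_MIR497A_01
miR-497a	DECOY_MIR497A_02
miR-497a	DECOY_MIR497A_03
miR-497a	DECOY_MIR497A_04
miR-497a	DECOY_MIR497A_05
miR-497a	Ep300
miR-497a	Erg
miR-497a	Ets1
miR-497a	Fli1
miR-497a	Hdac2
miR-497a	Ikzf1
miR-497a	Max
miR-497a	Med1
miR-497a	Myc
miR-497a	Nelfe
miR-497a	Nr1d1
miR-497a	Nr3c1
miR-497a	Otx2
miR-497a	Pou5f1
miR-497a	Pparg
miR-497a	Rad21
miR-497a	Rela
miR-497a	Smarca4
miR-497a	Spi1
miR-497a	Stat5a
miR-497a	Suz12
miR-497a	Tfap4
miR-497a	Zfp281
miR-497a	Zfp384
miR-511	Batf
miR-511	Btaf1
miR-511	Cebpa
miR-511	Cebpb
miR-511	DECOY_MIR511_01
miR-511	DECOY_MIR511_02
miR-511	DECOY_MIR511_03
miR-511	DECOY_MIR511_04
miR-511	DECOY_MIR511_05
miR-511	Fli1
miR-511	Mafb
miR-511	Nr3c1
miR-511	Rela
miR-511	Spi1
miR-511	Stat5a
miR-511	Tcf12
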