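strain_id,species,rep_profile,oxa51,oxa23,carbapenem,phage_id,call,eop
AB01,A. baumannii,3,1,1,R,Acibel004,propagates,1.0
AB02,A. baumannii,2,1,1,R,Acibel004,propagates,2.3e-03
AB03,A. baumannii,1,1,1,R,Acibel004,propagates,1.2e-02
AB04,A. baumannii,2,1,1,S,Acibel004,propagates,5.6e-04
AB05,A. baumannii,5,1,0,S,Acibel004,propagates,1.3e-05
AB06,A. baumannii,5,1,1,R,Acibel004,propagates,9.0e-05
AB07,A. baumannii,1,1,0,R,Acibel004,propagates,4.9e-04
AB08,A. baumannii,3,1,0,R,Acibel004,propagates,2.6e-01
AB09,A. baumannii,5,1,0,R,Acibel004,propagates,3.1e-05
AB10,A. baumannii,1,1,0,S,Acibel004,propagates,1.7e-05
AB11,A. baumannii,5,1,0,S,Acibel004,propagates,2.5e-03
AB12,A. baumannii,2,1,0,S,Acibel004,propagates,2.5e-01
AB13,A. baumannii,4,1,1,R,Acibel004,propagates,2.9e-01
AB14,A. baumannii,1,1,1,R,Acibel004,propagates,5.2e-05
AB15,A. baumannii,5,1,0,R,Acibel004,propagates,7.9e-01
AB16,A. baumannii,1,1,1,S,Acibel004,propagates,1.2e-01
AB17,A. baumannii,1,1,1,R,Acibel004,propagates,5.7e-05
AB18,A. baumannii,4,1,1,R,Acibel004,propagates,2.9e-05
AB19,A. baumannii,5,1,1,R,Acibel004,propagates,1.5e-04
AB20,A. baumannii,1,1,1,R,Acibel004,propagates,5.2e-02
AB21,A. baumannii,5,1,1,S,Acibel004,propagates,2.0e-01
AB22,A. baumannii,2,1,0,S,Acibel004,resistant,
AB23,A. baumannii,1,1,1,S,Acibel004,adsorbs_only,
AB24,A. baumannii,5,1,0,R,Acibel004,adsorbs_only,
AB25,A. baumannii,2,1,0,S,Acibel004,adsorbs_only,
AB26,A. baumannii,3,1,1,R,Acibel004,adsorbs_only,
AB27,A. baumannii,5,1,1,S,Acibel004,resistant,
AB28,A. baumannii,3,1,1,R,Acibel004,resistant,
AP01,A. pittii,1,0,1,R,Acibel004,adsorbs_only,
AP02,A. pittii,4,0,0,R,Acibel004,adsorbs_only,
AP03,A. pittii,5,0,1,R,Acibel004,adsorbs_only,
AP04,A. pittii,5,0,0,R,Acibel004,resistant,
AN01,A. nosocomialis,5,0,0,S,Acibel004,adsorbs_only,
AN02,A. nosocomialis,2,0,0,R,Acibel004,adsorbs_only,
AB01,A. baumannii,3,1,1,R,Acibel007,propagates,1.0
AB02,A. baumannii,2,1,1,R,Acibel007,propagates,2.5e-01
AB03,A. baumannii,1,1,1,R,Acibel007,propagates,4.9e-01
AB04,A. baumannii,2,1,1,S,Acibel007,propagates,5.0e-01
AB05,A. baumannii,5,1,0,S,Acibel007,propagates,1.8e-01
AB06,A. baumannii,5,1,1,R,Acibel007,propagates,4.6e-01
AB07,A. baumannii,1,1,0,R,Acibel007,propagates,6.1e-01
AB08,A. baumannii,3,1,0,R,Acibel007,propagates,1.2e-01
AB09,A. baumannii,5,1,0,R,Acibel007,propagates,2.3e-01
AB10,A. baumannii,1,1,0,S,Acibel007,propagates,2.3e-01
AB11,A. baumannii,5,1,0,S,Acibel007,propagates,2.9e-01
AB12,A. baumannii,2,1,0,S,Acibel007,propagates,3.2e-01
AB13,A. baumannii,4,1,1,R,Acibel007,propagates,4.6e-01
AB14,A. baumannii,1,1,1,R,Acibel007,propagates,1.6e-01
AB15,A. baumannii,5,1,0,R,Acibel007,propagates,1.3e-01
AB16,A. baumannii,1,1,1,S,Acibel007,adsorbs_only,
AB17,A. baumannii,1,1,1,R,Acibel007,adsorbs_only,
AB18,A. baumannii,4,1,1,R,Acibel007,adsorbs_only,
AB19,A. baumannii,5,1,1,R,Acibel007,resistant,
AB20,A. baumannii,1,1,1,R,Acibel007,resistant,
AB21,A. baumannii,5,1,1,S,Acibel007,resistant,
AB22,A. baumannii,2,1,0,S,Acibel007,propagates,2.2e-01
AB23,A. baumannii,1,1,1,S,Acibel007,propagates,5.9e-01
AB24,A. baumannii,5,1,0,R,Acibel007,resistant,
AB25,A. baumannii,2,1,0,S,Acibel007,resistant,
AB26,A. baumannii,3,1,1,R,Acibel007,resistant,
AB27,A. baumannii,5,1,1,S,Acibel007,resistant,
AB28,A. baumannii,3,1,1,R,Acibel007,resistant,
AP01,A. pittii,1,0,1,R,Acibel007,resistant,
AP02,A. pittii,4,0,0,R,Acibel007,resistant,
AP03,A. pittii,5,0,1,R,Acibel007,resistant,
AP04,A. pittii,5,0,0,R,Acibel007,resistant,
AN01,A. nosocomialis,5,0,0,S,Acibel007,resistant,
AN02,A. nosocomialis,2,0,0,R,Acibel007,resistant,
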