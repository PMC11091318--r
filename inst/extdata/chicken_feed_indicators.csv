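# Published mass-balance performance indicators of BSF larvae reared on
# chicken feed or similar substrates, harvested around prepupation.
# xmax_ww_mg / xmax_dw_mg: maximal larval wet / dry weight where reported.
# derived: fields read from graphs or derived from the identities
# SCE = 1/SCR = BR/SRR rather than reported directly.
study,feed,xmax_ww_mg,xmax_dw_mg,br,sce,scr,srr,derived
study_01,chicken feed,NA,33.9,NA,0.23,NA,NA,
study_02,chicken feed,251,NA,0.13,0.15,NA,0.85,sce
study_03,hen feed,229,NA,NA,0.27,NA,NA,
study_04,chicken feed,NA,55.6,0.21,0.32,NA,0.68,
study_05,chicken starter mash,148.4,NA,0.18,0.35,NA,0.50,sce
study_06,chicken feed,NA,69,NA,0.34,NA,NA,
study_07,broiler feed,216.2,NA,NA,0.48,NA,0.44,
study_08,chicken feed,NA,66,NA,0.38,NA,0.66,
study_09,chicken feed,NA,NA,0.08,0.16,NA,NA,br;sce
study_10,chicken feed,191,NA,NA,0.27,3.75,0.64,xmax_ww;sce;scr;srr
study_11,chicken feed,80,NA,NA,0.14,NA,0.43,xmax_ww
study_12,chicken feed,NA,NA,0.18,0.41,2.4,0.44,sce;scr;srr
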