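Th17	synthetic placeholder immune set	IMM_TH17_01	IMM_TH17_02	IMM_TH17_03	IMM_TH17_04	IMM_TH17_05	IMM_TH17_06	IMM_TH17_07	IMM_TH17_08	IMM_TH17_09	IMM_TH17_10	IMM_TH17_11	IMM_TH17_12	IMM_TH17_13	IMM_TH17_14	IMM_TH17_15
Th2	synthetic placeholder immune set	IMM_TH2_01	IMM_TH2_02	IMM_TH2_03	IMM_TH2_04	IMM_TH2_05	IMM_TH2_06	IMM_TH2_07	IMM_TH2_08	IMM_TH2_09	IMM_TH2_10	IMM_TH2_11	IMM_TH2_12	IMM_TH2_13	IMM_TH2_14	IMM_TH2_15
Treg	synthetic placeholder immune set	IMM_TREG_01	IMM_TREG_02	IMM_TREG_03	IMM_TREG_04	IMM_TREG_05	IMM_TREG_06	IMM_TREG_07	IMM_TREG_08	IMM_TREG_09	IMM_TREG_10	IMM_TREG_11	IMM_TREG_12	IMM_TREG_13	IMM_TREG_14	IMM_TREG_15
CD8	synthetic placeholder immune set	IMM_CD8_01	IMM_CD8_02	IMM_CD8_03	IMM_CD8_04	IMM_CD8_05	IMM_CD8_06	IMM_CD8_07	IMM_CD8_08	IMM_CD8_09	IMM_CD8_10	IMM_CD8_11	IMM_CD8_12	IMM_CD8_13	IMM_CD8_14	IMM_CD8_15
APM	synthetic placeholder immune set	IMM_APM_01	IMM_APM_02	IMM_APM_03	IMM_APM_04	IMM_APM_05	IMM_APM_06	IMM_APM_07	IMM_APM_08	IMM_APM_09	IMM_APM_10	IMM_APM_11	IMM_APM_12	IMM_APM_13	IMM_APM_14	IMM_APM_15
Angiogenesis	synthetic placeholder immune set	IMM_ANGIOGENESIS_01	IMM_ANGIOGENESIS_02	IMM_ANGIOGENESIS_03	IMM_ANGIOGENESIS_04	IMM_ANGIOGENESIS_05	IMM_ANGIOGENESIS_06	IMM_ANGIOGENESIS_07	IMM_ANGIOGENESIS_08	IMM_ANGIOGENESIS_09	IMM_ANGIOGENESIS_10	IMM_ANGIOGENESIS_11	IMM_ANGIOGENESIS_12	IMM_ANGIOGENESIS_13	IMM_ANGIOGENESIS_14	IMM_ANGIOGENESIS_15
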