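organism,metabolism,yield_value,yield_sd
synthetic_AOA_1,ammonia_oxidation,0.00893,0.0008
synthetic_AOA_2,ammonia_oxidation,0.00850,0.0011
synthetic_NOB_1,nitrite_oxidation,0.00323,0.0015
synthetic_NOB_2,nitrite_oxidation,0.00280,0.0019
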