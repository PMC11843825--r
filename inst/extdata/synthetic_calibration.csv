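class,day,vHb_1,vHb_2,vHb_3,vHb_4,vHb_5,vHb_6,xHbO2_1,xHbO2_2,xHbO2_3,xHbO2_4,xHbO2_5,xHbO2_6,sd
2a,0,0.35,0.35,0.3,0.3,0.22,0.22,0.45,0.45,0.5239,0.5239,0.5977,0.5977,0.05
2a,1,0.45,0.45,0.4,0.4,0.4,0.4,0.5,0.5,0.5923,0.5923,0.6846,0.6846,0.08
2a,2,0.5,0.5,0.45,0.45,0.58,0.58,0.53,0.53,0.6147,0.6147,0.6994,0.6994,0.05
2a,3,0.5,0.5,0.45,0.45,0.7,0.7,0.55,0.55,0.6341,0.6341,0.7183,0.7183,0.02
2b1,0,0.3,0.3,0.28,0.28,0.2,0.2,0.42,0.42,0.4964,0.4964,0.5727,0.5727,0.04
2b1,1,0.38,0.38,0.34,0.34,0.34,0.34,0.46,0.46,0.5563,0.5563,0.6526,0.6526,0.08
2b1,2,0.42,0.42,0.38,0.38,0.45,0.45,0.48,0.48,0.5759,0.5759,0.6718,0.6718,0.07
2b1,3,0.44,0.44,0.4,0.4,0.52,0.52,0.5,0.5,0.5932,0.5932,0.6864,0.6864,0.04
2b2,0,0.18,0.46,0.4,0.22,0.18,0.18,0.4,0.4,0.4769,0.4769,0.5539,0.5539,0.03
2b2,1,0.18,0.46,0.4,0.22,0.22,0.22,0.41,0.41,0.4927,0.4927,0.5755,0.5755,0.03
2b2,2,0.18,0.46,0.4,0.22,0.25,0.25,0.42,0.42,0.5108,0.5108,0.6016,0.6016,0.03
2b2,3,0.18,0.46,0.4,0.22,0.28,0.28,0.42,0.42,0.5177,0.5177,0.6153,0.6153,0.03
3,0,0.18,0.18,0.16,0.16,0.15,0.15,0.3,0.3,0.3912,0.3912,0.4824,0.4824,0.035
3,1,0.16,0.16,0.14,0.14,0.12,0.12,0.28,0.28,0.3755,0.3755,0.4709,0.4709,0.04
3,2,0.14,0.14,0.12,0.12,0.1,0.1,0.26,0.26,0.3533,0.3533,0.4467,0.4467,0.045
3,3,0.12,0.12,0.11,0.11,0.085,0.085,0.24,0.24,0.3241,0.3241,0.4082,0.4082,0.05
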