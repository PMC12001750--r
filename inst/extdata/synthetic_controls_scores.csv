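sample_id,group,signal_score,gas_score,protein17_score
CTRL01,control,0.02,0.11,0.05
CTRL02,control,0.04,0.06,0.12
CTRL03,control,0.05,0.19,0.02
CTRL04,control,0.06,0.27,0.31
CTRL05,control,0.07,0.08,0.09
CTRL06,control,0.08,0.14,0.22
CTRL07,control,0.09,0.33,0.07
CTRL08,control,0.1,0.05,0.41
CTRL09,control,0.11,0.22,0.16
CTRL10,control,0.12,0.41,0.03
CTRL11,control,0.13,0.09,0.55
CTRL12,control,0.14,0.16,0.11
CTRL13,control,0.15,0.3,0.27
CTRL14,control,0.16,0.12,0.08
CTRL15,control,0.18,0.46,0.62
CTRL16,control,0.19,0.07,0.14
CTRL17,control,0.2,0.24,0.36
CTRL18,control,0.22,0.52,0.04
CTRL19,control,0.24,0.1,0.19
CTRL20,control,0.26,0.36,0.48
CTRL21,control,0.28,0.18,0.1
CTRL22,control,0.3,0.78,0.25
CTRL23,control,0.32,0.13,0.06
CTRL24,control,0.34,0.44,0.71
CTRL25,control,0.37,0.21,0.13
CTRL26,control,0.4,0.57,0.33
CTRL27,control,0.43,0.15,0.18
CTRL28,control,0.46,0.63,0.44
CTRL29,control,0.5,0.26,0.09
CTRL30,control,0.55,0.85,0.58
CTRL31,control,0.61,0.38,0.28
CTRL32,control,0.68,0.49,0.83
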