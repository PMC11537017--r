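label,microbiota,metabolite,or_total,or_total_low,or_total_high,or_step1,or_step1_low,or_step1_high,or_step2,or_step2_low,or_step2_high
PWY6708_4hydroxyphenylacetate,PWY.6708 ubiquinol-8 biosynthesis (prokaryotic),4-hydroxyphenylacetate levels,1.149,1.022,1.291,1.112,1.010,1.225,1.214,1.070,1.379
Odoribacter_palmitoleate,genus Odoribacter,palmitoleate (16:1n7) levels,1.260,1.044,1.523,1.128,1.011,1.260,1.143,1.005,1.299
Odoribacter_phosphate_to_alanine,genus Odoribacter,phosphate to alanine ratio,1.260,1.044,1.523,1.137,1.013,1.276,1.153,1.009,1.318
Coprococcus_X12839,Coprococcus sp ART55/1,X-12839 levels,1.125,1.010,1.253,1.103,1.004,1.213,1.107,1.018,1.203
Coprococcus_phosphate_to_alanine,Coprococcus sp ART55/1,phosphate to alanine ratio,1.125,1.010,1.253,1.092,1.016,1.175,1.153,1.009,1.318
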