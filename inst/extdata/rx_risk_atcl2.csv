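condition,codes,concordance
Cardiovascular/cerebrovascular diseases and heart diseases,"C01, C04, C05, C07, C08, B01",concordant
Hypertension,"C02, C03, C09",concordant
Hyperlipidemia,C10,concordant
Hyperuricemia/Gout,M04,concordant
Infectious diseases,J01-J07,discordant
Acid related disorders,A02,discordant
Inflammatory/Rheumatic disorders,"M01-M03, M09",discordant
Corticosteroid-responsive diseases,H02,discordant
Nutrition-related diseases,"A08-A09, A11-A16",discordant
"Pain, including migraine",N02,discordant
Depression and other mental disorders,"N06, N07",discordant
Chronic obstructive airways diseases,R03,discordant
Gastrointestinal disorders and nausea,"A03-A04, A06-A07",discordant
Anemia,B03,discordant
"Diseases of the genito-urinary system, including benign prostatic hypertrophy",G01-G04,discordant
Thyroid disorders,H03,discordant
Respiratory diseases,"R01-R02, R05-R07",discordant
Epilepsy,N03,discordant
"Dermatological diseases, including psoriasis",D01-D11,discordant
"Eye disorders, including glaucoma","S01, S03",discordant
Psychotic illnesses,N05,discordant
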