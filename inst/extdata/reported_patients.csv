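# Originally reported per-patient values, retained for cross-checking.
# flag: ok | bsa_typo (reported BSA inconsistent with the Du Bois formula on the recorded height/weight) | inconsistent (corrupted record block).
"patient_id","bsa_m2_reported","tbsa_pct_reported","delta_tbsa_reported","flag"
"P01",1.79,2,1.388,"ok"
"P02",1.88,3,1.816,"ok"
"P03",2.14,3,1.632,"ok"
"P04",2.22,3,0.721,"ok"
"P05",2.15,6,1.145,"inconsistent"
"P06",1.97,4,3.119,"inconsistent"
"P07",2.49,2,0.536,"bsa_typo"
"P08",2.32,1,0.246,"ok"
"P09",2.28,30,12.941,"ok"
"P10",1.77,6,3.732,"ok"
"P11",2.28,6,2.357,"ok"
"P12",1.99,9,7.055,"ok"
"P13",2.11,8,4.464,"ok"
"P14",1.99,9,6.397,"ok"
"P15",2.37,1,0.073,"ok"
"P16",1.99,1,0.118,"ok"
"P17",2.98,14,9.196,"bsa_typo"
"P18",2.05,6,2.729,"ok"
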