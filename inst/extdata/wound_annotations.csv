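# Pilot burn cohort: per-wound clinical annotations.
# excluded = TRUE marks wounds whose originally reported derived values are internally inconsistent with their own scan areas.
"patient_id","location","mechanism","degree","surgery","excluded","note"
"P01","RLL","scald","II and III",1,FALSE,""
"P01","LLL","scald","II and III",1,FALSE,""
"P02","RUL","fire","IIa",0,FALSE,""
"P02","LUL","fire","IIa",0,FALSE,""
"P03","LLL","fire","III",0,FALSE,""
"P03","RUL","fire","III",0,FALSE,""
"P03","LUL","fire","III",0,FALSE,""
"P04","Torso","scald","IIa",0,FALSE,""
"P04","RUL","scald","IIa",0,FALSE,""
"P04","LUL","scald","IIa",0,TRUE,"reported percent reduction 27.6 is a dropped-digit typo for 27.06"
"P04","LLL","scald","IIa",0,FALSE,""
"P05","LUL","fire","IIa",0,FALSE,"mechanism follows the cohort summary counts; the per-wound record block for this patient is corrupted in the source"
"P05","RUL","fire","IIa",0,FALSE,"mechanism follows the cohort summary counts; the per-wound record block for this patient is corrupted in the source"
"P06","LUL","explosion","IIb",0,TRUE,"reported dA/percent belong to a shifted row; recomputed values differ"
"P06","RUL","explosion","IIb",0,FALSE,""
"P07","LUL","explosion","IIa",0,TRUE,"reported dA/percent belong to a shifted row; recomputed values differ"
"P07","RUL","explosion","IIa",0,FALSE,""
"P08","LUL","explosion","IIb",0,FALSE,""
"P09","Torso","fire","I and IIb",0,FALSE,""
"P09","RUL","fire","I and IIb",0,FALSE,""
"P09","LUL","fire","I and IIb",0,FALSE,""
"P09","RLL","fire","I and IIb",0,FALSE,""
"P09","LLL","fire","I and IIb",0,FALSE,""
"P10","Torso","scald","I-III",1,FALSE,""
"P10","RUL","scald","I-III",1,FALSE,""
"P10","RLL","scald","I-III",1,FALSE,""
"P10","LUL","scald","I-III",1,FALSE,""
"P11","Torso","explosion","IIb and III",0,FALSE,""
"P11","RUL","explosion","IIb and III",0,FALSE,""
"P12","RLL","scald","IIb",1,FALSE,""
"P12","LLL","scald","IIb",1,FALSE,""
"P13","Torso","scald","IIb",0,FALSE,""
"P13","LUL","scald","IIb",0,FALSE,""
"P14","RUL","scald","IIa",1,FALSE,""
"P14","LUL","scald","IIa",1,FALSE,""
"P15","LLL","scald","IIb",0,FALSE,""
"P16","RLL","fire","III",1,FALSE,""
"P17","Torso","explosion","I and IIa",0,FALSE,""
"P17","RUL","explosion","I and IIa",0,FALSE,""
"P17","RLL","explosion","I and IIa",0,FALSE,""
"P18","RLL","explosion","I and IIa",0,FALSE,""
"P18","RUL","explosion","I and IIa",0,FALSE,""
"P18","LUL","explosion","I and IIa",0,FALSE,""
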