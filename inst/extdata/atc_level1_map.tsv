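drugname	atc1
OMEPRAZOLE	A
ONDANSETRON	A
HEPARIN	B
FILGRASTIM	B
AMLODIPINE	C
METOPROLOL	C
NOREPINEPHRINE	C
MUPIROCIN	D
HYDROCORTISONE TOPICAL	D
OXYTOCIN	G
ESTRADIOL	G
DEXAMETHASONE	H
METHYLPREDNISOLONE	H
VANCOMYCIN	J
MEROPENEM	J
ACYCLOVIR	J
CYCLOPHOSPHAMIDE	L
FLUDARABINE	L
RITUXIMAB	L
TOCILIZUMAB	L
IBUPROFEN	M
BACLOFEN	M
LEVETIRACETAM	N
MORPHINE	N
LORAZEPAM	N
IVERMECTIN	P
ALBENDAZOLE	P
SALBUTAMOL	R
MONTELUKAST	R
TIMOLOL EYE DROPS	S
CONTRAST MEDIA AGENT	V
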