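Route	intravenous
Route	oral
Route	subcutaneous
Route	intramuscular
Route	topical
Route	inhaled
Route	transdermal
Route	intrathecal
Route	rectal
Route	sublingual
Route	intravenous infusion
Route	intravenous bolus
Route	nasogastric
Route	ophthalmic
Route	by mouth
Route	intra-arterial
Frequency	once daily
Frequency	twice daily
Frequency	three times daily
Frequency	four times daily
Frequency	every 8 hours
Frequency	every 12 hours
Frequency	every 6 hours
Frequency	once weekly
Frequency	twice weekly
Frequency	every other day
Frequency	every three weeks
Frequency	once monthly
Frequency	as needed
Frequency	at bedtime
Frequency	every morning
Duration	three days
Duration	five days
Duration	seven days
Duration	ten days
Duration	fourteen days
Duration	two weeks
Duration	three weeks
Duration	four weeks
Duration	six weeks
Duration	two months
Duration	three months
Duration	six months
Duration	one year
Duration	three hour
Duration	two hours
Duration	one week
Duration	48 hours
Duration	24 hours
Duration	several weeks
Duration	six cycles
Indication	ovarian cancer
Indication	breast cancer
Indication	lung cancer
Indication	colorectal cancer
Indication	prostate cancer
Indication	lymphoma
Indication	leukemia
Indication	multiple myeloma
Indication	melanoma
Indication	rheumatoid arthritis
Indication	systemic lupus
Indication	psoriasis
Indication	crohn disease
Indication	ulcerative colitis
Indication	asthma
Indication	chronic obstructive airway disease
Indication	community acquired bacterial illness
Indication	urinary tract colonization
Indication	type 2 diabetes
Indication	essential blood pressure elevation
Indication	dyslipidemia
Indication	epilepsy
Indication	migraine prophylaxis
Indication	bipolar disorder
Indication	schizophrenia
Indication	major depressive episode
Indication	generalized worry disorder
Indication	gastroesophageal reflux
Indication	peptic ulcer disease
Indication	atrial arrhythmia
Indication	coronary artery disease
Indication	venous thromboembolism prophylaxis
Indication	organ transplant rejection
Indication	hypothyroid state
Indication	osteopenia
Indication	gouty arthropathy
Indication	glaucoma
Indication	chronic viral liver disease
Indication	hiv disease
Indication	tuberculosis
OSSD	obesity
OSSD	smoking history
OSSD	alcohol use
OSSD	elevated troponin t level
OSSD	left ventricular hypertrophy
OSSD	mild splenomegaly
OSSD	hepatomegaly
OSSD	lymphadenopathy
OSSD	pallor
OSSD	diaphoresis
OSSD	tachypnea
OSSD	borderline bilirubin
OSSD	elevated creatinine at baseline
OSSD	low baseline hemoglobin
OSSD	chronic lower back discomfort
OSSD	degenerative joint changes
OSSD	mild cognitive decline
OSSD	hearing aid use
OSSD	cataract
OSSD	presbyopia
OSSD	benign prostatic enlargement
OSSD	varicose veins
OSSD	hiatal hernia
OSSD	diverticulosis
OSSD	cholelithiasis
OSSD	renal cyst
OSSD	thyroid nodule
OSSD	mitral valve prolapse
OSSD	heart murmur
OSSD	sinus arrhythmia on ecg
OSSD	seasonal rhinitis
OSSD	eczema history
OSSD	childhood measles
OSSD	prior appendectomy
OSSD	prior cholecystectomy
OSSD	postmenopausal state
OSSD	gravida two para two
OSSD	sedentary lifestyle
OSSD	poor dentition
OSSD	family history of malignancy
Treatment	blood transfusion
Treatment	red packed cells
Treatment	platelet transfusion
Treatment	intravenous fluids
Treatment	fluids
Treatment	oxygen therapy
Treatment	mechanical ventilation
Treatment	hemodialysis
Treatment	plasmapheresis
Treatment	supportive care
Treatment	bowel rest
Treatment	wound debridement
Treatment	surgical drainage
Treatment	chest physiotherapy
Treatment	cardioversion
Treatment	defibrillation
Treatment	pacing
Treatment	physical therapy
Treatment	occupational therapy
Treatment	splinting
Treatment	cold compresses
Treatment	warm compresses
Treatment	elevation of the limb
Treatment	pressure dressing
Treatment	observation in hospital
Treatment	admission to intensive care
Treatment	endoscopic hemostasis
Treatment	stent placement
Treatment	radiotherapy
Treatment	granulocyte support
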