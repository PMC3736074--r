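# synthetic fixture domain lexicon: term<TAB>semantic-type code
# terms are 1-3 word phrases, lowercase; codes follow the 20 health-related semantic types
her2 protein	Aapp
estrogen receptor	Aapp
progesterone receptor	Aapp
brca1 protein	Aapp
insulin	Aapp
hemoglobin	Aapp
albumin	Aapp
antibody	Aapp
growth factor	Aapp
ca 125	Aapp
lymphedema	Acab
scar tissue	Acab
seroma	Acab
keloid	Acab
contracture	Acab
adhesion	Acab
fibrosis	Acab
stenosis	Acab
breast asymmetry	Anab
cyst	Anab
polyp	Anab
fistula	Anab
hernia	Anab
lesion	Anab
lymphatic system	Bdsy
immune system	Bdsy
endocrine system	Bdsy
nervous system	Bdsy
circulatory system	Bdsy
chest wall	Blor
armpit	Blor
left breast	Blor
right breast	Blor
upper back	Blor
abdomen	Blor
scalp	Blor
collarbone	Blor
oncology	Bmod
radiology	Bmod
pathology	Bmod
immunology	Bmod
plastic surgery	Bmod
physical therapy	Bmod
genetics	Bmod
lymph node	Bpoc
breast tissue	Bpoc
milk duct	Bpoc
ovary	Bpoc
thyroid gland	Bpoc
liver	Bpoc
bone marrow	Bpoc
sentinel node	Bpoc
areola	Bpoc
nipple	Bpoc
mammogram	Diap
biopsy	Diap
ultrasound	Diap
mri scan	Diap
pet scan	Diap
ct scan	Diap
bone scan	Diap
blood test	Diap
genetic test	Diap
breast exam	Diap
echocardiogram	Diap
breast cancer	Dsyn
diabetes	Dsyn
hypertension	Dsyn
osteoporosis	Dsyn
anemia	Dsyn
lymphoma	Dsyn
heart disease	Dsyn
arthritis	Dsyn
hypothyroidism	Dsyn
shingles	Dsyn
estrogen	Horm
progesterone	Horm
tamoxifen citrate	Horm
thyroxine	Horm
cortisol	Horm
insulin hormone	Horm
herceptin	Imft
interferon	Imft
vaccine	Imft
immunoglobulin	Imft
trastuzumab	Imft
radiation burn	Inpo
needle stick	Inpo
bruise	Inpo
sprain	Inpo
overdose	Inpo
allergic reaction	Inpo
blood count	lbpr
tumor marker	lbpr
liver panel	lbpr
white count	lbpr
platelet count	lbpr
hormone panel	lbpr
depression	Mobd
anxiety	Mobd
insomnia	Mobd
panic disorder	Mobd
chemo brain	Mobd
post traumatic stress	Mobd
mood disorder	Mobd
tumor	Neop
carcinoma	Neop
metastasis	Neop
dcis	Neop
invasive ductal carcinoma	Neop
lobular carcinoma	Neop
sarcoma	Neop
recurrence	Neop
taxol	Orch
adriamycin	Orch
cytoxan	Orch
carboplatin	Orch
doxorubicin	Orch
paclitaxel	Orch
methotrexate	Orch
fluorouracil	Orch
inflammation	Patf
necrosis	Patf
edema	Patf
neutropenia	Patf
neuropathy	Patf
hot flash	Patf
bone loss	Patf
hair loss	Patf
tamoxifen	Phsu
arimidex	Phsu
femara	Phsu
aromasin	Phsu
zometa	Phsu
neulasta	Phsu
benadryl	Phsu
ativan	Phsu
aspirin	Phsu
ibuprofen	Phsu
morphine	Phsu
zofran	Phsu
fatigue	Sosy
nausea	Sosy
pain	Sosy
swelling	Sosy
fever	Sosy
headache	Sosy
dizziness	Sosy
rash	Sosy
itching	Sosy
numbness	Sosy
tenderness	Sosy
night sweats	Sosy
chemotherapy	Topp
mastectomy	Topp
lumpectomy	Topp
radiation therapy	Topp
reconstruction	Topp
hormone therapy	Topp
surgery	Topp
port placement	Topp
infusion	Topp
acupuncture	Topp
massage therapy	Topp
stem cell transplant	Topp
estrogen	Phsu
herceptin	Phsu
insulin	Horm
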