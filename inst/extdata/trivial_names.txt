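# Common/trivial chemical and drug names used by the synthetic corpus
# generator and as seed entries for test lexicons.
aspirin
ibuprofen
paracetamol
caffeine
nicotine
morphine
codeine
penicillin
amoxicillin
erythromycin
tetracycline
streptomycin
insulin
heparin
warfarin
metformin
atorvastatin
simvastatin
omeprazole
ranitidine
cimetidine
diazepam
lorazepam
midazolam
haloperidol
clozapine
olanzapine
risperidone
fluoxetine
sertraline
paroxetine
venlafaxine
imipramine
amitriptyline
lithium
valproate
carbamazepine
phenytoin
lamotrigine
gabapentin
pregabalin
levodopa
dopamine
serotonin
histamine
adrenaline
noradrenaline
acetylcholine
glutamate
glycine
taurine
creatine
carnitine
choline
inositol
biotin
riboflavin
thiamine
niacin
folate
cobalamin
ascorbate
tocopherol
retinol
calciferol
menadione
cholesterol
cortisol
estradiol
progesterone
testosterone
aldosterone
thyroxine
melatonin
prostaglandin
leukotriene
thromboxane
ethanol
methanol
glycerol
sorbitol
mannitol
xylitol
sucrose
glucose
fructose
lactose
maltose
galactose
ribose
starch
cellulose
glycogen
chitin
urea
uric acid
lactic acid
citric acid
acetic acid
formic acid
oxalic acid
malic acid
tartaric acid
succinic acid
fumaric acid
pyruvate
oxaloacetate
citrate
malate
acetate
propionate
butyrate
palmitate
stearate
oleate
linoleate
arachidonate
cisplatin
carboplatin
oxaliplatin
doxorubicin
daunorubicin
paclitaxel
docetaxel
vincristine
vinblastine
etoposide
irinotecan
topotecan
methotrexate
fluorouracil
gemcitabine
capecitabine
cyclophosphamide
ifosfamide
tamoxifen
letrozole
anastrozole
imatinib
gefitinib
erlotinib
sorafenib
sunitinib
dexamethasone
prednisolone
hydrocortisone
budesonide
salbutamol
salmeterol
theophylline
montelukast
loratadine
cetirizine
fexofenadine
chlorpheniramine
pseudoephedrine
dextromethorphan
guaifenesin
naloxone
naltrexone
buprenorphine
methadone
fentanyl
ketamine
propofol
lidocaine
bupivacaine
procaine
atropine
scopolamine
pilocarpine
physostigmine
neostigmine
digoxin
amiodarone
verapamil
diltiazem
nifedipine
amlodipine
losartan
valsartan
captopril
enalapril
lisinopril
propranolol
atenolol
metoprolol
carvedilol
furosemide
hydrochlorothiazide
spironolactone
allopurinol
colchicine
probenecid
sulfasalazine
mesalazine
azathioprine
mercaptopurine
tacrolimus
sirolimus
ciclosporin
mycophenolate
rituximab
infliximab
adalimumab
quercetin
resveratrol
curcumin
capsaicin
menthol
camphor
limonene
pinene
taxol
penicillamine
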