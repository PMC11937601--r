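a
abdomen
abdominal
abnormal
abnormality
abscess
absent
ache
acidosis
acute
acutely
adjacent
admission
admitted
advised
aeration
afebrile
after
air
airspace
airway
airways
albumin
alert
alveolar
ambulatory
an
and
anemia
antibiotic
antibiotics
antiviral
aorta
aortic
apex
apical
appearance
appears
appetite
are
arrived
arterial
aspiration
asthma
asymmetric
at
atelectasis
attending
atypical
auscultation
azithromycin
bacteremia
bacteria
bacterial
basal
base
baseline
be
been
bilateral
biopsy
blood
bloods
blunting
body
border
both
breath
breathing
bronchial
bronchiectasis
bronchitis
bronchograms
bronchoscopy
bronchus
bruising
calcification
calcified
cannula
capacity
cardiac
cardiomediastinal
cardiopulmonary
carina
case
catheter
cavitary
cavitation
cavity
cell
central
cessation
change
changes
chest
chill
chills
chronic
chronicity
cilia
clear
clinic
clinical
clinically
clubbing
clustered
coarse
collapse
column
community
comorbid
comparison
complete
compromise
computed
concern
confirmed
confluent
congestion
consistent
consolidation
consolidative
contact
contacts
contour
contours
contrast
control
convalescent
coronavirus
correlation
cough
course
crackle
crackles
crazy
culture
cyanosis
cystic
daily
day
days
decompensation
decreased
deficit
degenerative
dehydration
demarcated
denies
dense
density
describes
deterioration
diabetes
diabetic
diaphragm
diaphragmatic
differential
diffuse
diffusely
dilated
diminished
discharge
discomfort
disease
distress
distributed
distribution
dominant
dose
drainage
drenching
dry
dullness
dyspnea
early
edema
edematous
effusion
effusions
eighty
elderly
elevated
emphysema
empiric
empyema
endemic
enlarged
eosinophil
episode
erythema
evening
exacerbation
examination
excellent
exercise
exertion
exposure
exposures
exudate
family
fatigue
favor
febrile
female
fever
fibronodular
fibrosis
fifty
findings
fissure
five
fluid
focal
follow
for
forty
four
fremitus
frequent
from
gas
gastric
general
glass
grade
gradual
granuloma
granulomatous
ground
had
has
have
haziness
hazy
headache
health
hemithorax
hemodynamically
hemoptysis
hepatic
high
highly
hilar
hilum
history
hospital
hydration
hypertension
hypoxia
identified
ill
illness
imaging
immunocompromised
impression
improved
in
include
includes
increased
indeterminate
indicate
infection
infectious
infiltrate
inflammation
inflammatory
influenza
inpatient
inspiratory
intensive
intermittent
interstitial
interval
intravenous
intubation
is
isolation
jugular
kidney
known
laboratory
large
lateral
left
lethargy
leukocytosis
lifelong
like
limits
lingula
lobar
lobe
lobes
loss
low
lower
lung
lungs
lymph
lymphadenopathy
lymphocyte
lymphopenia
malaise
male
management
margin
marked
mass
may
mediastinal
mediastinum
medical
medication
medications
members
metabolic
micronodular
midline
mild
mildly
moderate
monitoring
months
morphology
most
mucus
multifocal
multilobar
murmur
muscle
myalgia
nasal
nausea
nebulizer
neutrophil
night
no
nodes
nodular
nodule
nodules
non
nonspecific
normal
noted
obscures
observation
occupational
of
old
on
one
onset
opacities
opacity
or
oral
organism
otherwise
over
oxygen
oxygenation
pain
palpation
parapneumonic
parenchyma
parenchymal
partially
past
patchy
patent
pathogen
patient
pattern
paving
percussion
performed
perfused
perfusion
peribronchial
pericardial
perihilar
peripheral
planned
pleura
pleural
pleurisy
pleuritic
pneumonia
pneumonic
pneumothorax
poor
portable
portion
position
posterior
posteroanterior
predominate
prescribed
present
presentation
presenting
preserved
pressure
prior
procalcitonin
productive
profile
prognosis
progressive
prominent
protein
pulmonary
pulse
purulent
pyrexia
quadrant
radiograph
radiographic
rale
rapid
rate
reactive
recent
recently
recommended
recovery
recumbent
reduced
referral
reflect
region
regions
regular
relatively
remains
renal
repeat
reported
reports
resolution
respiration
respiratory
retraction
reveals
review
rhinorrhea
rhonchi
rib
right
rigors
room
rounded
routine
saline
sample
satellite
saturation
scan
scarring
scattered
secretion
sedation
seen
segment
segmental
segments
sepsis
septal
seventy
several
severe
severity
shadow
shallow
shortness
show
shows
sick
significant
signs
silhouette
similar
since
sinus
six
sixty
sleep
small
smear
smell
smoker
sore
sounds
spared
specimen
spine
sputum
stable
status
sternal
steroid
streaked
streaky
stridor
study
subcutaneous
subpleural
suggestive
supine
supplemental
suspected
suspicious
swab
sweats
symptom
symptoms
syndrome
tachycardia
tachycardic
tachypnea
taste
temperature
ten
tenderness
test
the
therapy
there
thick
thickening
thin
thirty
this
thoracic
thorax
three
throat
to
tolerance
tomography
trachea
tracheal
transfer
travel
treatment
tree
tuberculosis
twenty
two
type
unchanged
unintentional
unremarkable
unwell
up
upper
vaccination
vascular
vasculature
ventilation
vessel
viral
vital
volume
vomiting
walled
ward
was
week
weeks
weight
well
wheeze
wheezing
widened
with
within
without
worsening
year
zone
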