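# Health-care-worker identification lexicon: term<TAB>class<TAB>acronym.
# class: occupation | degree | association.
# acronym = 1 marks short tokens matched exact-case as standalone tokens
# (e.g. "MD" matches, "md"/"Md" do not); all other terms match
# case-insensitively at word boundaries.
doctor	occupation	0
nurse	occupation	0
physician	occupation	0
surgeon	occupation	0
paramedic	occupation	0
pharmacist	occupation	0
psychiatrist	occupation	0
psychologist	occupation	0
pediatrician	occupation	0
cardiologist	occupation	0
anesthesiologist	occupation	0
dentist	occupation	0
midwife	occupation	0
hospitalist	occupation	0
oncologist	occupation	0
radiologist	occupation	0
neurologist	occupation	0
nurse practitioner	occupation	0
physician assistant	occupation	0
respiratory therapist	occupation	0
registered nurse	occupation	0
medical student	occupation	0
emergency physician	occupation	0
icu nurse	occupation	0
MD	degree	1
DO	degree	1
RN	degree	1
NP	degree	1
PA	degree	1
EMT	degree	1
LPN	degree	1
CRNA	degree	0
DNP	degree	0
BSN	degree	0
MSN	degree	0
MBBS	degree	0
DDS	degree	0
DMD	degree	0
PharmD	degree	0
Doctor of Medicine	degree	0
FACP	association	0
FACS	association	0
FAAP	association	0
FACC	association	0
FACEP	association	0
FCCP	association	0
FASN	association	0
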