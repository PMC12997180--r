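# Starter diagnosis alias table. Keys are canonical labels; values are
# synonyms. Keys and values are canonicalized on load, so natural spellings
# are fine. Extend freely; merging via this table is transitive.
familial mediterranean fever:
  - fmf
  - recurrent polyserositis
  - periodic fever syndrome
mcardle disease:
  - glycogen storage disease v
  - glycogen storage disease type v
  - myophosphorylase deficiency
wilsons disease:
  - wilson disease
  - hepatolenticular degeneration
behcets disease:
  - behcet syndrome
  - behcets syndrome
  - adamantiades behcet disease
iga nephropathy:
  - bergers disease
  - berger disease
dementia with lewy bodies:
  - lewy body dementia
  - diffuse lewy body disease
parkinsons disease:
  - parkinson disease
  - idiopathic parkinsonism
hereditary hemochromatosis:
  - hemochromatosis
  - iron overload disorder
acute intermittent porphyria:
  - acute porphyria
autoimmune encephalitis:
  - antibody mediated encephalitis
g6pd deficiency:
  - glucose 6 phosphate dehydrogenase deficiency
deep vein thrombosis:
  - dvt
congestive heart failure:
  - chf
  - heart failure
atrial fibrillation:
  - afib
post traumatic stress disorder:
  - ptsd
methamphetamine induced psychotic disorder:
  - methamphetamine induced psychosis
  - stimulant induced psychosis
viral myocarditis:
  - myocarditis viral
hiv aids:
  - aids
  - hiv
  - hiv infection
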