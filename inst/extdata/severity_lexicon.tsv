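# Three-tier toy side-effect severity lexicon (term<TAB>weight).
# Tiers: mild = 1, moderate = 2, severe = 3. Terms are lower-cased,
# lemmatized single tokens.
nausea	1
headache	1
drowsiness	1
dizziness	1
itching	1
fatigue	1
rash	1
sweating	1
constipation	1
diarrhea	1
heartburn	1
insomnia	1
flushing	1
yawning	1
dryness	1
sneezing	1
vomiting	2
tremor	2
confusion	2
palpitation	2
fainting	2
swelling	2
fever	2
hypertension	2
anxiety	2
agitation	2
weakness	2
jaundice	2
tinnitus	2
hive	2
blistering	2
seizure	3
hemorrhage	3
anaphylaxis	3
arrhythmia	3
hallucination	3
stroke	3
hepatotoxicity	3
angioedema	3
bleeding	3
coma	3
overdose	3
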