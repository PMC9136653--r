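term,class,category,source
blunted,AFFECT,DESCRIPTIVE,affect descriptive characteristic
broad,AFFECT,DESCRIPTIVE,affect descriptive characteristic
flat,AFFECT,DESCRIPTIVE,affect descriptive characteristic
restricted,AFFECT,DESCRIPTIVE,affect descriptive characteristic
constricted,AFFECT,DESCRIPTIVE,affect descriptive characteristic
less constricted,AFFECT,DESCRIPTIVE,affect descriptive characteristic
mood congruent,AFFECT,DESCRIPTIVE,affect descriptive characteristic
topic congruent,AFFECT,DESCRIPTIVE,affect descriptive characteristic
appropriate to thought/speech content,AFFECT,DESCRIPTIVE,affect descriptive characteristic
inappropriate to content,AFFECT,DESCRIPTIVE,affect descriptive characteristic
wide ranging,AFFECT,DESCRIPTIVE,affect descriptive characteristic
reactive,AFFECT,DESCRIPTIVE,affect descriptive characteristic
euthymic,AFFECT,DESCRIPTIVE,affect descriptive characteristic
dysthymic,AFFECT,DESCRIPTIVE,affect descriptive characteristic
intensity,AFFECT,DESCRIPTIVE,affect descriptive characteristic
neither increased nor decreased,AFFECT,DESCRIPTIVE,affect descriptive characteristic
irritable,AFFECT,DESCRIPTIVE,affect descriptive characteristic
nervous,AFFECT,DESCRIPTIVE,affect descriptive characteristic
anxious,AFFECT,DESCRIPTIVE,affect descriptive characteristic
sad,AFFECT,DESCRIPTIVE,affect descriptive characteristic
angry,AFFECT,DESCRIPTIVE,affect descriptive characteristic
tense,AFFECT,DESCRIPTIVE,affect descriptive characteristic
labile,AFFECT,DESCRIPTIVE,affect descriptive characteristic
within normal limits,AFFECT,DESCRIPTIVE,affect descriptive characteristic
crying,AFFECT,BEHAVIORAL,affect behavioral characteristic
laughing,AFFECT,BEHAVIORAL,affect behavioral characteristic
smiling,AFFECT,BEHAVIORAL,affect behavioral characteristic
sweating,AFFECT,PHYSIOLOGICAL,affect physiological characteristic
rapid respiration,AFFECT,PHYSIOLOGICAL,affect physiological characteristic
tearful,AFFECT,DESCRIPTIVE,note excerpt descriptor
melancholic,AFFECT,DESCRIPTIVE,note excerpt descriptor
depressed,MOOD,DESCRIPTIVE,mood descriptive characteristic
low,MOOD,DESCRIPTIVE,mood descriptive characteristic
dysphoric,MOOD,DESCRIPTIVE,mood descriptive characteristic
anxious,MOOD,DESCRIPTIVE,mood descriptive characteristic
irritable,MOOD,DESCRIPTIVE,mood descriptive characteristic
euphoric,MOOD,DESCRIPTIVE,mood descriptive characteristic
angry,MOOD,DESCRIPTIVE,mood descriptive characteristic
anhedonia,MOOD,DESCRIPTIVE,note excerpt descriptor
moody,MOOD,DESCRIPTIVE,note excerpt descriptor
unhappy,MOOD,DESCRIPTIVE,note excerpt descriptor
mood swings,MOOD,DESCRIPTIVE,note excerpt descriptor
emotional numbing,MOOD,DESCRIPTIVE,note excerpt descriptor
improved,,CHANGE,comparative change marker
better,,CHANGE,comparative change marker
less,,CHANGE,comparative change marker
brighter,,CHANGE,comparative change marker
broader,,CHANGE,comparative change marker
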