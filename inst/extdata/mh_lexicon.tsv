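# Representative mental-health lexicon: term<TAB>subgroup.
# Subgroups: anxiety | depression | insomnia | addiction.
# Terms are matched case-insensitively at word boundaries after NFKC
# normalization; multi-word phrases match as contiguous token sequences.
# A term listed under several subgroups maps to the union of them.
# This file is swappable: pass any file in the same format to the loaders.
anxiety	anxiety
anxious	anxiety
anxiousness	anxiety
panic	anxiety
panic attack	anxiety
panic attacks	anxiety
panicking	anxiety
worried	anxiety
worrying	anxiety
worries	anxiety
nervous	anxiety
nervousness	anxiety
on edge	anxiety
uneasy	anxiety
dread	anxiety
fearful	anxiety
phobia	anxiety
agoraphobia	anxiety
social anxiety	anxiety
health anxiety	anxiety
obsessive compulsive	anxiety
stressed	anxiety
stressed out	anxiety
overwhelmed	anxiety
freaking out	anxiety
jittery	anxiety
restless	anxiety
heart racing	anxiety
hyperventilating	anxiety
terrified	anxiety
paranoid	anxiety
paranoia	anxiety
ptsd	anxiety
mental breakdown	anxiety
depression	depression
depressed	depression
depressing	depression
hopeless	depression
hopelessness	depression
worthless	depression
despair	depression
miserable	depression
suicidal	depression
suicide	depression
self harm	depression
lonely	depression
loneliness	depression
cant stop crying	depression
numb	depression
empty inside	depression
no motivation	depression
burnout	depression
burned out	depression
grief	depression
grieving	depression
heartbroken	depression
sadness	depression
low mood	depression
feeling down	depression
feeling blue	depression
want to die	depression
mental breakdown	depression
antidepressant	depression
antidepressants	depression
prozac	depression
zoloft	depression
sertraline	depression
fluoxetine	depression
insomnia	insomnia
insomniac	insomnia
sleepless	insomnia
sleeplessness	insomnia
sleepless night	insomnia
sleepless nights	insomnia
cant sleep	insomnia
no sleep	insomnia
up all night	insomnia
wide awake	insomnia
cant fall asleep	insomnia
sleep deprived	insomnia
sleep deprivation	insomnia
melatonin	insomnia
ambien	insomnia
nightmares	insomnia
night terrors	insomnia
tossing and turning	insomnia
lying awake	insomnia
addiction	addiction
addicted	addiction
addict	addiction
addicts	addiction
alcoholism	addiction
alcoholic	addiction
relapse	addiction
relapsed	addiction
withdrawal	addiction
overdose	addiction
overdosed	addiction
substance abuse	addiction
drug abuse	addiction
binge drinking	addiction
drinking too much	addiction
sober	addiction
sobriety	addiction
rehab	addiction
detox	addiction
opioid	addiction
opioids	addiction
heroin	addiction
nicotine	addiction
chain smoking	addiction
gambling addiction	addiction
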