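# Synset membership (word<TAB>node): maps surface words, including slang
# variants common in drug-related comments, onto mini-taxonomy concept
# nodes. Every node name is implicitly also a member of its own synset.
# A word may map to several nodes (polysemy); similarity takes the best
# sense pair. Synthetic fixture; not extracted from WordNet.
dizzy	dizziness
lightheaded	dizziness
vertigo	dizziness
puke	vomiting
puked	vomiting
puking	vomiting
vomit	vomiting
vomited	vomiting
nauseous	nausea
nauseated	nausea
queasy	nausea
cramps	abdominal_pain
stomachache	abdominal_pain
trippin	hallucination
tripping	hallucination
hallucinating	hallucination
hallucinations	hallucination
visuals	hallucination
numb	numbness
numbs	numbness
tingly	sensory_change
slurred	slurred_speech
slurring	slurred_speech
wobbly	ataxia
stumbling	ataxia
staggering	ataxia
racing	tachycardia
heartracing	tachycardia
buzzed	euphoria
euphoric	euphoria
jittery	agitation
restless	agitation
agitated	agitation
paranoid	psychosis
blackout	psychosis
floating	depersonalization
detached	depersonalization
outofbody	depersonalization
depersonalized	depersonalization
dissociated	dissociation
dissociates	dissociation
dissociating	dissociation
bleed	bleeding
oded	overdose
overdosed	overdose
od	overdose
heavy	heaviness
weed	cannabis
marijuana	cannabis
pot	cannabis
drunk	ethanol
alcohol	ethanol
booze	ethanol
dxm	dextromethorphan
robo	dextromethorphan
speed	amphetamine
ket	ketamine
vid	video
vids	video
clip	video
movie	video
show	video
channel	video
song	music
tune	music
beat	music
band	music
guitar	music
drums	music
concert	party
rave	party
partying	party
syrup	bottle
chug	bottle
coffee	bottle
water	bottle
bird	penguin
dog	animal
cat	animal
fish	animal
house	artifact
room	artifact
door	artifact
window	artifact
table	artifact
chair	artifact
lamp	artifact
mirror	artifact
couch	artifact
floor	artifact
wall	artifact
ceiling	artifact
phone	artifact
computer	artifact
keyboard	artifact
screen	artifact
camera	artifact
picture	artifact
photo	artifact
book	artifact
shirt	artifact
shoes	artifact
ticket	artifact
bus	artifact
train	artifact
plane	artifact
food	artifact
pizza	artifact
candy	artifact
school	place
work	place
town	place
city	place
street	place
road	place
store	place
beach	place
lake	place
mountain	place
garden	place
kitchen	place
bridge	place
river	place
island	place
forest	place
field	place
corner	place
rain	object
snow	object
wind	object
fire	object
cloud	object
moon	object
star	object
grass	object
tree	object
light	object
sound	object
voice	object
face	object
hand	object
head	object
mouth	object
money	object
story	object
comment	object
account	object
internet	object
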