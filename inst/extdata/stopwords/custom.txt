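# Custom stopwords: punctuation-elision variants of standard stopwords
# (apostrophes are deleted during normalisation, so "don't" reaches the
# matcher as "dont") plus canonical internet abbreviations. This list is the
# package's own; it is not identical to any previously published list.
dont
cant
wont
didnt
doesnt
isnt
arent
wasnt
werent
couldnt
shouldnt
wouldnt
hasnt
havent
hadnt
aint
im
ive
id
ill
youre
youve
youll
youd
hes
shes
weve
theyre
theyve
thats
whats
theres
heres
lets
its
gonna
wanna
gotta
kinda
sorta
lol
lmao
lmfao
rofl
jk
ftw
omg
wtf
brb
btw
imo
imho
tbh
smh
idk
irl
afaik
thx
ty
np
pls
plz
ur
u
r
ya
yea
yeah
nah
haha
hahaha
hehe
xd
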