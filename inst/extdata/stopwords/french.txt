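# French stopwords (ASCII-folded forms included since preprocessing strips
# non-ASCII characters before matching)
au
aux
avec
ce
ces
dans
de
des
du
elle
en
et
eux
il
ils
je
la
le
les
leur
lui
ma
mais
mes
moi
mon
ne
nos
notre
nous
ou
par
pas
pour
qu
que
qui
sa
se
ses
son
sur
ta
te
tes
toi
ton
tu
un
une
vos
votre
vous
cet
cette
ete
etee
etees
etes
etant
suis
es
est
sommes
sont
serai
seras
sera
serons
serez
seront
etais
etait
etions
etiez
etaient
fus
fut
furent
ai
avons
avez
ont
aura
auras
aurons
aurez
auront
avais
avait
avions
aviez
avaient
eu
eue
eues
eus
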