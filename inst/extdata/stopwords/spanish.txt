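# Spanish stopwords (ASCII-folded forms included since preprocessing strips
# non-ASCII characters before matching)
de
la
que
el
en
y
a
los
del
se
las
por
un
para
con
una
su
al
lo
como
mas
pero
sus
le
ya
o
este
si
porque
esta
entre
cuando
muy
sin
sobre
tambien
me
hasta
hay
donde
quien
desde
todo
nos
durante
todos
uno
les
ni
contra
otros
ese
eso
ante
ellos
e
esto
mi
antes
algunos
unos
yo
otro
otras
otra
tanto
esa
estos
mucho
quienes
nada
muchos
cual
poco
ella
estar
estas
algunas
algo
nosotros
tu
te
ti
tus
ellas
nosotras
vosotros
vosotras
os
mio
mia
mios
mias
tuyo
tuya
suyo
suya
estoy
estas
esta
estamos
estan
ser
soy
eres
es
somos
son
tengo
tiene
tenemos
tienen
fue
era
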