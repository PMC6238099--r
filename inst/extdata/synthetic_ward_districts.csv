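prefix,district
dar,Dar es Salaam
kino,Dar es Salaam
dodo,Dodoma
mwan,Mwanza
arus,Arusha
mbey,Mbeya
kigo,Kigoma
tang,Tanga
njom,Njombe
irin,Iringa
geit,Geita
moro,Morogoro
pwan,Pwani
simi,Simiyu
ruvu,Ruvuma
sing,Singida
mjin,Mjini Magharibi
mara,Mara
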