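rplp1
rpl36a
rpl22l1
rps19
rps2
mrpl4
shank3
homer1
dlgap1
grin2b
camk2a
syngap1
dlg4
ctnnb1
drd1
ppp1r1b
gfap
syt1
syp
snap25
stx1a
vamp2
syn1
syn2
bsn
pclo
nrxn1
nlgn1
gria1
gria2
grm5
gabra1
gad1
gad2
th
slc6a3
slc17a7
calb1
calb2
pvalb
penk
pdyn
tac1
adora2a
drd2
gpr88
rgs9
arpp21
pde10a
ppp3ca
prkcb
camk4
nefl
nefm
map2
tubb3
actn2
sptbn1
ank2
cacna1b
kcnj4
scn2a
atp2b2
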