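AABR07005593.1
AABR07013843.1
AABR07016578.1
AABR07016845.1
AABR07018064.1
AABR07027811.4
AABR07048271.1
AC096809.1
AC097129.1
AC123253.2
Adamts18
Adgb
Adra2a
Akr1b8
Anxa8
Apcdd1l
Arl5c
Armc3
Atp2a3
Bard1
Barhl1
Batf
Bdnf
Bub1b
Capsl
Cbln2
Ccdc108
Ccdc184
Ccdc33
Ccdc74a
Cd164l2
Cep55
Cfap44
Cldn15
Cpne4
Cxcr5
Dlec1
Dlx2
Dnai1
E2f1
Etv5
Fam64a
Fbxo47
Ggnbp1
Glis1
Gsto2
Hcrt
Hes1
Hes7
Hist1h2ac
Hist1h2ac
Hist1h2ao
Hist1h2bl
Hist1h2bo
Hist3h3
Hrct1
Hs3st5
Hsd17b3
Il2rb
Ildr2
Itgb4
Kcnh2
Kcnk12
Kcnk4
Kcp
Kif2c
Klhdc7a
Lhb
LOC100361018
LOC499781
LOC502684
LOC684762
LOC686662
LOC688553
Lrfn1
Lrp2
Lrrc36
Map3k19
Mfsd4
MGC116202
Mmp14
Mms22l
Myb
Mypn
Nr2e3
Otx1
Oxtr
Pcbd1
Pcdh12
Pla2g2c
Plagl1
Plch1
Plekha7
Prlhr
Prss56
Ptger3
Rab38
Reep6
RGD1562029
Rgs6
Rnf182
Rspo3
Rxfp2
Scd4
Sec14l4
Sfrp2
Shc3
Sidt1
Slc17a7
Slc28a3
Slc29a1
Slc6a12
Smoc2
Spag8
Spata18
Spats1
Spred3
Sprn
Srrm4
Synpo2l
T2
Tcte1
Tgm2
Tmem37
Tox2
Trpv2
Tsnaxip1
Tspo
Ttc16
Ttll6
Vsx1
Vwa3b
Vwa5b1
Xkr7
Zic5
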