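id,compound,pka_OH_m,pka_OH_p,pka_RH,pka_RH2,sigma_p,substituent
1,4-Tert-butylcatechol,8.24,13.51,NA,NA,-0.20,tBu
2,4-Methylcatechol,9.23,13.33,NA,NA,-0.17,Me
3,4-Ethylcatechol,8.29,13.42,NA,NA,-0.15,Et
4,"3,4-Dihydroxydihydrocinnamic acid",6.83,11.76,4.88,NA,-0.07,CH2CH2COOH
5,"3,4-Dihydroxyphenylacetic acid",10.09,12.07,4.98,NA,NA,CH2COOH
6,Catechol,8.82,13.07,NA,NA,0,H
7,Norepinephrine,13.41,8.59,10.41,NA,0.09,CH(OH)CH2NH2
8,"1,2,4-Benzenetriol",9.26,11.13,12.60,NA,-0.37,OH
9,Caffeic acid,12.50,8.50,3.92,NA,0.09,CH=CHCOOH
10,Dopamine,13.7,8.66,11.01,NA,0.17,CH2CH2NH2
11,4-Chlorocatechol,8.13,10.41,NA,NA,0.23,Cl
12,Epinephrine,13.08,8.65,10.89,NA,0.3,CH(OH)CH2NHMe
13,"3,4-Dihydroxybenzaldehyde",11.78,8.71,NA,NA,0.42,CHO
14,"3,4-Dihydroxybenzoic acid",11.79,9.11,3.22,NA,0.45,COOH
15,"3,4-Dihydroxybenzylamine",13.07,5.62,9.01,NA,0.53,CH2NH2
16,"3,4-Dihydroxybenzonitrile",11.79,6.54,NA,NA,0.66,CN
17,4-Nitrocatechol,11.15,6.10,NA,NA,0.78,NO2
18,Adrenalone,11.96,5.16,7.24,NA,NA,C(O)CH2NHMe
19,Dopa,13.6,8.86,2.31,10.2,NA,CH2CH(NH2)COOH
20,Catechin,8.61,9.38,11.61,NA,NA,fused-chromane
21,Quercetin,6.78,11.56,9.17,NA,NA,fused-chromone
22,Chlorogenic acid,11.53,8.11,3.43,NA,NA,CH=CHCOO-quinyl
23,Isoprenaline,8.52,10.06,NA,NA,NA,CH(OH)CH2NHiPr
24,Nordihydroguaiaretic acid,9.30,14.31,NA,NA,NA,CH2CH(Me)R
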