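chain,site,class,WT_mean,WT_sd,Het_mean,Het_sd,KO_mean,KO_sd
alpha1(I),Lys-87,Lys,0.2,0.0,0.2,0.0,80.8,2.4
alpha1(I),Lys-87,Hyl,1.8,0.3,1.7,0.1,3.7,0.4
alpha1(I),Lys-87,G-Hyl,3.5,0.3,3.6,0.2,0.8,0.0
alpha1(I),Lys-87,GG-Hyl,94.5,0.5,94.6,0.3,14.7,2.0
alpha1(I),Lys-99,Lys,82.5,0.3,83.3,1.7,90.7,1.6
alpha1(I),Lys-99,Hyl,13.2,0.3,12.6,0.9,3.8,0.5
alpha1(I),Lys-99,G-Hyl,3.6,0.4,3.4,0.7,2.8,0.4
alpha1(I),Lys-99,GG-Hyl,0.8,0.2,0.7,0.1,2.8,0.8
alpha1(I),Lys-174,Lys,65.2,1.4,66.7,0.8,73.9,3.6
alpha1(I),Lys-174,Hyl,32.7,0.9,31.6,0.7,18.6,1.7
alpha1(I),Lys-174,G-Hyl,1.5,0.4,1.3,0.1,2.4,0.3
alpha1(I),Lys-174,GG-Hyl,0.6,0.2,0.5,0.1,5.1,1.6
alpha1(I),Lys-219,Lys,88.6,0.3,89.0,0.4,89.5,1.3
alpha1(I),Lys-219,Hyl,11.4,0.3,11.0,0.4,10.5,1.3
alpha1(I),Lys-564,Lys,76.8,0.9,76.4,1.2,48.8,5.7
alpha1(I),Lys-564,Hyl,19.2,0.3,19.5,1.1,21.5,0.4
alpha1(I),Lys-564,G-Hyl,2.7,0.4,2.8,0.1,9.8,0.7
alpha1(I),Lys-564,GG-Hyl,1.3,0.3,1.4,0.0,19.9,5.0
alpha1(I),Lys-603,Lys,13.9,0.2,15.1,0.8,15.7,0.2
alpha1(I),Lys-603,Hyl,84.7,0.2,83.4,0.9,81.9,0.4
alpha1(I),Lys-603,G-Hyl,0.9,0.0,0.9,0.1,0.9,0.0
alpha1(I),Lys-603,GG-Hyl,0.5,0.0,0.6,0.0,1.5,0.4
alpha2(I),Lys-87,Lys,2.8,0.4,4.7,1.0,70.7,4.2
alpha2(I),Lys-87,Hyl,97.2,0.4,95.3,1.0,29.3,4.2
alpha2(I),Lys-174,Lys,38.9,3.4,37.4,3.3,91.8,1.4
alpha2(I),Lys-174,Hyl,7.1,0.7,6.1,1.1,0.5,0.0
alpha2(I),Lys-174,G-Hyl,45.2,3.3,48.3,3.4,4.7,0.6
alpha2(I),Lys-174,GG-Hyl,8.8,0.8,8.3,0.9,3.0,0.9
alpha2(I),Lys-219,Lys,63.8,1.2,65.5,1.0,62.2,6.2
alpha2(I),Lys-219,Hyl,32.4,0.7,30.0,0.8,24.0,1.6
alpha2(I),Lys-219,G-Hyl,1.7,0.2,2.1,0.3,2.0,0.3
alpha2(I),Lys-219,GG-Hyl,2.2,0.3,2.5,0.2,11.7,4.3
alpha1(I),Lys-918/930,Lys + Lys,0.0,0.0,0.0,0.0,66.4,2.3
alpha1(I),Lys-918/930,Lys + Hyl,4.1,0.2,4.1,0.2,26.6,1.4
alpha1(I),Lys-918/930,Hyl + Hyl,95.9,0.2,95.9,0.2,7.0,1.0
alpha2(I),Lys-933,Lys,0.0,0.0,0.0,0.0,69.6,5.3
alpha2(I),Lys-933,Hyl,90.6,2.2,93.0,2.3,28.1,4.8
alpha2(I),Lys-933,G-Hyl,9.4,2.2,7.0,2.3,2.3,0.5
alpha2(I),Lys-933,GG-Hyl,0.0,0.0,0.0,0.0,0.0,0.0
alpha1(I),Lys-9N,Lys,100.0,0.0,100.0,0.0,100.0,0.0
alpha1(I),Lys-9N,Hyl,0.0,0.0,0.0,0.0,0.0,0.0
alpha1(I),Lys-16C,Lys,100.0,0.0,100.0,0.0,100.0,0.0
alpha1(I),Lys-16C,Hyl,0.0,0.0,0.0,0.0,0.0,0.0
alpha2(I),Lys-5N,Lys,100.0,0.0,100.0,0.0,100.0,0.0
alpha2(I),Lys-5N,Hyl,0.0,0.0,0.0,0.0,0.0,0.0
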