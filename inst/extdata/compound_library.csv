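number,name,class,novelty,rt_min,ion_formula,measured_mz,calc_mz,ppm_error
1,Griseofulvin,PKS,known,11.42,C17H18ClO6,353.0793,353.0786,-1.98
2,Dechlorogriseofulvin,PKS,known,10.01,C17H19O6,319.1173,319.1176,0.94
3,Cytochalasin D,PKS-NRPS,known,11.81,C30H38NO6,508.2687,508.2694,1.38
4,Zygosporin E,PKS-NRPS,known,13.94,C30H38NO5,492.2742,492.2744,0.41
5,Epoxycytochalasin D,PKS-NRPS,known,10.87,C30H38NO7,524.2651,524.2661,1.91
6,Hirsutatin A,NRPS,known,15.85,C34H53N4O10,677.3741,677.3756,2.21
7,Piliformic acid,PKS,known,10.84,C11H18O4Na,237.1094,237.1097,1.27
8,"2,3-dihydro-2,4-dimethylbenzofuran-7-carboxylic acid",PKS,known,11.15,C11H13O3,193.0857,193.0859,1.04
9,Cyclic pentapeptide 1,NRPS,known,16.20,C32H50N5O5,584.3816,584.3806,-1.71
10,Xylarotide A,NRPS,known,15.97,C29H52N5O5,550.3973,550.3963,-1.82
11,Cyclic pentapeptide 2,NRPS,known,14.28,C28H50N5O5,536.3819,536.3806,-2.42
12,Ellisiiamide A,NRPS,new,14.76,C30H46N5O5,556.3501,556.3493,-1.44
13,Ellisiiamide B,NRPS,new,15.19,C31H48N5O5,570.3656,570.3650,-1.05
14,Ellisiiamide C,NRPS,new,17.04,C33H52N5O5,598.3968,598.3963,-0.84
15,Ellisiiamide D,NRPS,new,14.47,C27H48N5O5,522.3662,522.3650,-2.30
16,Ellisiiamide E,NRPS,new,16.89,C30H54N5O5,564.4132,564.4119,-2.30
17,Ellisiiamide F,NRPS,new,14.11,C31H48N5O6,586.3616,586.3599,-1.72
18,Ellisiiamide G,NRPS,new,14.00,C32H50N5O6,600.3768,600.3756,-2.00
19,Ellisiiamide H,NRPS,new,14.89,C33H52N5O6,614.3936,614.3912,-2.41
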