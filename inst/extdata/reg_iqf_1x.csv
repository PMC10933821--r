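balance,term,reg,ratio_printed
1-H,"V_xc(A,B)",0.05,99
1-H,"V_xc(C,D)",0.07,64
1-H,"V_xc(E,F)",0.10,46
1-H,"V_cl(A,B)",0.67,7
1-H,"V_cl(C,D)",-0.05,-91
1-H,"V_cl(E,F)",0.02,220
1-Me,"V_xc(A,B)",0.21,17
1-Me,"V_xc(C,D)",0.33,11
1-Me,"V_xc(E,F)",0.06,59
1-Me,"V_cl(A,B)",2.07,2
1-Me,"V_cl(C,D)",0.28,13
1-Me,"V_cl(E,F)",0.30,12
1-OMe,"V_xc(A,B)",0.06,66
1-OMe,"V_xc(C,D)",0.19,21
1-OMe,"V_xc(E,F)",0.18,23
1-OMe,"V_cl(A,B)",1.05,4
1-OMe,"V_cl(C,D)",0.28,15
1-OMe,"V_cl(E,F)",0.21,20
1-NMe2,"V_xc(A,B)",0.05,82
1-NMe2,"V_xc(C,D)",0.10,37
1-NMe2,"V_xc(E,F)",0.27,14
1-NMe2,"V_cl(A,B)",3.28,1
1-NMe2,"V_cl(C,D)",0.55,7
1-NMe2,"V_cl(E,F)",0.32,12
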