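balance,term,reg,ratio_printed
2-NO2,"V_xc(A,B)",0.22,30
2-NO2,"V_xc(C,D)",0.19,34
2-NO2,"V_xc(E,F)",0.31,21
2-NO2,"V_cl(A,B)",2.67,2
2-NO2,"V_cl(C,D)",0.00,-2256
2-NO2,"V_cl(E,F)",-0.12,-54
2-CN,"V_xc(A,B)",0.21,31
2-CN,"V_xc(C,D)",0.18,35
2-CN,"V_xc(E,F)",0.27,24
2-CN,"V_cl(A,B)",2.64,2
2-CN,"V_cl(C,D)",0.03,226
2-CN,"V_cl(E,F)",-0.10,-62
2-H,"V_xc(A,B)",0.19,36
2-H,"V_xc(C,D)",0.12,55
2-H,"V_xc(E,F)",0.22,31
2-H,"V_cl(A,B)",2.55,3
2-H,"V_cl(C,D)",-0.08,-87
2-H,"V_cl(E,F)",-0.07,-105
2-OMe,"V_xc(A,B)",0.18,37
2-OMe,"V_xc(C,D)",0.13,53
2-OMe,"V_xc(E,F)",0.17,41
2-OMe,"V_cl(A,B)",2.57,3
2-OMe,"V_cl(C,D)",-0.08,-86
2-OMe,"V_cl(E,F)",-0.18,-38
2-NMe2,"V_xc(A,B)",0.17,42
2-NMe2,"V_xc(C,D)",0.09,83
2-NMe2,"V_xc(E,F)",0.09,76
2-NMe2,"V_cl(A,B)",2.42,3
2-NMe2,"V_cl(C,D)",-0.11,-62
2-NMe2,"V_cl(E,F)",-0.14,-50
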