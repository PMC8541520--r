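experiment,shot,camera,r2,recordedRank
1,1,DSLR,0.9962,1
1,2,AR0130,0.9866,3
1,3,DSLR,0.9947,2
2,1,AR0130,0.9884,2
2,2,DSLR,0.9995,1
2,3,AR0130,0.9793,3
3,1,AR0130,0.995,1
3,2,IMX179,0.9944,2
3,3,AR0130,0.9943,3
4,1,IMX179,0.9561,3
4,2,AR0130,0.9952,1
4,3,IMX179,0.9942,2
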