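parameter,stage,mean,sd
Np,MS1,3.66,1.39
Np,MS2,3.92,1.26
Np,MS3,4.40,1.48
Np,MS4,4.58,1.65
Np,MS5,4.18,1.29
Bf,MS1,50.42,11.30
Bf,MS2,54.24,9.14
Bf,MS3,58.18,9.67
Bf,MS4,59.82,12.49
Bf,MS5,56.78,14.29
Bdc,MS1,20.04,8.10
Bdc,MS2,20.88,7.18
Bdc,MS3,20.21,6.65
Bdc,MS4,22.93,9.23
Bdc,MS5,18.82,8.66
E,MS1,98.11,16.90
E,MS2,104.92,15.04
E,MS3,105.68,13.20
E,MS4,111.32,18.59
E,MS5,103.70,17.84
Be,MS1,13.75,5.30
Be,MS2,14.74,4.16
Be,MS3,16.71,5.17
Be,MS4,16.66,5.20
Be,MS5,16.60,6.56
De,MS1,36.01,9.08
De,MS2,72.93,11.76
De,MS3,77.82,14.14
De,MS4,80.74,15.26
De,MS5,78.30,17.29
Th,MS1,2.19,0.26
Th,MS2,3.17,0.27
Th,MS3,3.22,0.26
Th,MS4,3.24,0.34
Th,MS5,3.27,0.33
Bd,MS1,0.53,0.11
Bd,MS2,0.54,0.08
Bd,MS3,0.57,0.09
Bd,MS4,0.55,0.08
Bd,MS5,0.57,0.12
Si,MS1,0.24,0.05
Si,MS2,0.17,0.03
Si,MS3,0.18,0.03
Si,MS4,0.17,0.03
Si,MS5,0.18,0.04
Ar,MS1,0.39,0.13
Ar,MS2,0.20,0.05
Ar,MS3,0.22,0.06
Ar,MS4,0.21,0.07
Ar,MS5,0.21,0.08
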