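weight_g,scale_reading,pressure_mmhg,volume_mm3
5.5,0,35.48,4
5.5,1,29.85,5.22
5.5,2,25.12,6.48
5.5,3,21.13,7.78
5.5,4,17.78,9.12
5.5,5,14.96,10.5
5.5,6,12.59,11.92
5.5,7,10.59,13.38
5.5,8,8.91,14.88
5.5,9,7.5,16.42
5.5,10,6.31,18
10,0,66.07,16
10,1,56.23,17.42
10,2,47.86,18.88
10,3,40.74,20.38
10,4,34.67,21.92
10,5,29.51,23.5
10,6,25.12,25.12
10,7,21.38,26.78
10,8,18.2,28.48
10,9,15.49,30.22
10,10,13.18,32
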