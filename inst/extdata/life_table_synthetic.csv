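sex,age,ex
male,0,72.77
male,1,71.94
male,2,71.1
male,3,70.27
male,4,69.43
male,5,68.59
male,6,67.74
male,7,66.9
male,8,66.06
male,9,65.21
male,10,64.36
male,11,63.51
male,12,62.66
male,13,61.81
male,14,60.95
male,15,60.1
male,16,59.24
male,17,58.38
male,18,57.52
male,19,56.66
male,20,55.8
male,21,54.94
male,22,54.08
male,23,53.21
male,24,52.35
male,25,51.48
male,26,50.61
male,27,49.75
male,28,48.88
male,29,48.01
male,30,47.14
male,31,46.27
male,32,45.4
male,33,44.53
male,34,43.66
male,35,42.8
male,36,41.93
male,37,41.06
male,38,40.2
male,39,39.33
male,40,38.47
male,41,37.6
male,42,36.74
male,43,35.89
male,44,35.03
male,45,34.18
male,46,33.33
male,47,32.48
male,48,31.64
male,49,30.8
male,50,29.96
male,51,29.13
male,52,28.3
male,53,27.48
male,54,26.67
male,55,25.86
male,56,25.06
male,57,24.26
male,58,23.47
male,59,22.69
male,60,21.92
male,61,21.16
male,62,20.41
male,63,19.66
male,64,18.93
male,65,18.21
male,66,17.5
male,67,16.8
male,68,16.11
male,69,15.44
male,70,14.78
male,71,14.13
male,72,13.5
male,73,12.88
male,74,12.28
male,75,11.69
male,76,11.12
male,77,10.56
male,78,10.02
male,79,9.5
male,80,8.99
male,81,8.5
male,82,8.03
male,83,7.58
male,84,7.14
male,85,6.72
male,86,6.32
male,87,5.94
male,88,5.57
male,89,5.22
male,90,4.88
male,91,4.56
male,92,4.26
male,93,3.98
male,94,3.71
male,95,3.45
male,96,3.21
male,97,2.98
male,98,2.77
male,99,2.57
male,100,2.38
male,101,2.21
male,102,2.05
male,103,1.89
male,104,1.75
male,105,1.61
male,106,1.48
male,107,1.35
male,108,1.21
male,109,1.02
male,110,0.7
female,0,79.9
female,1,78.94
female,2,77.98
female,3,77.03
female,4,76.07
female,5,75.11
female,6,74.15
female,7,73.19
female,8,72.23
female,9,71.28
female,10,70.32
female,11,69.36
female,12,68.4
female,13,67.44
female,14,66.48
female,15,65.52
female,16,64.56
female,17,63.6
female,18,62.64
female,19,61.68
female,20,60.72
female,21,59.76
female,22,58.8
female,23,57.84
female,24,56.88
female,25,55.92
female,26,54.96
female,27,54
female,28,53.04
female,29,52.09
female,30,51.13
female,31,50.17
female,32,49.22
female,33,48.27
female,34,47.31
female,35,46.36
female,36,45.41
female,37,44.47
female,38,43.52
female,39,42.58
female,40,41.64
female,41,40.7
female,42,39.76
female,43,38.83
female,44,37.89
female,45,36.97
female,46,36.04
female,47,35.12
female,48,34.21
female,49,33.29
female,50,32.39
female,51,31.49
female,52,30.59
female,53,29.7
female,54,28.81
female,55,27.94
female,56,27.07
female,57,26.2
female,58,25.35
female,59,24.5
female,60,23.66
female,61,22.83
female,62,22.01
female,63,21.21
female,64,20.41
female,65,19.62
female,66,18.85
female,67,18.09
female,68,17.34
female,69,16.6
female,70,15.88
female,71,15.18
female,72,14.49
female,73,13.81
female,74,13.15
female,75,12.51
female,76,11.89
female,77,11.28
female,78,10.69
female,79,10.12
female,80,9.56
female,81,9.03
female,82,8.51
female,83,8.02
female,84,7.54
female,85,7.08
female,86,6.64
female,87,6.22
female,88,5.82
female,89,5.44
female,90,5.07
female,91,4.73
female,92,4.4
female,93,4.09
female,94,3.8
female,95,3.53
female,96,3.27
female,97,3.02
female,98,2.8
female,99,2.58
female,100,2.39
female,101,2.2
female,102,2.03
female,103,1.87
female,104,1.72
female,105,1.58
female,106,1.45
female,107,1.32
female,108,1.18
female,109,1
female,110,0.69
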