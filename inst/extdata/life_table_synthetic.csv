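# synthetic reference life table (NOT real registry data):
# smooth residual life expectancy by sex and single age 0-100,
# two editions emulating a 2010 and a 2019 national table
sex,age,e2010,e2019
female,0,79.9,82.5
female,1,78.81,81.38
female,2,77.73,80.26
female,3,76.65,79.15
female,4,75.58,78.04
female,5,74.51,76.94
female,6,73.45,75.84
female,7,72.4,74.75
female,8,71.34,73.67
female,9,70.3,72.59
female,10,69.26,71.51
female,11,68.22,70.44
female,12,67.19,69.38
female,13,66.16,68.32
female,14,65.14,67.26
female,15,64.13,66.21
female,16,63.12,65.17
female,17,62.11,64.13
female,18,61.11,63.1
female,19,60.12,62.08
female,20,59.13,61.06
female,21,58.15,60.04
female,22,57.17,59.03
female,23,56.2,58.03
female,24,55.23,57.03
female,25,54.27,56.04
female,26,53.32,55.05
female,27,52.37,54.07
female,28,51.43,53.1
female,29,50.49,52.13
female,30,49.56,51.17
female,31,48.63,50.21
female,32,47.71,49.26
female,33,46.79,48.32
female,34,45.89,47.38
female,35,44.98,46.45
female,36,44.09,45.52
female,37,43.2,44.6
female,38,42.31,43.69
female,39,41.43,42.78
female,40,40.56,41.88
female,41,39.69,40.99
female,42,38.83,40.1
female,43,37.98,39.22
female,44,37.13,38.34
female,45,36.29,37.47
female,46,35.46,36.61
female,47,34.63,35.76
female,48,33.81,34.91
female,49,33,34.07
female,50,32.19,33.23
female,51,31.39,32.41
female,52,30.59,31.59
female,53,29.8,30.77
female,54,29.02,29.97
female,55,28.25,29.17
female,56,27.48,28.38
female,57,26.72,27.59
female,58,25.97,26.81
female,59,25.22,26.04
female,60,24.49,25.28
female,61,23.75,24.53
female,62,23.03,23.78
female,63,22.32,23.04
female,64,21.61,22.31
female,65,20.91,21.59
female,66,20.21,20.87
female,67,19.53,20.16
female,68,18.85,19.46
female,69,18.18,18.77
female,70,17.52,18.09
female,71,16.87,17.42
female,72,16.22,16.75
female,73,15.59,16.09
female,74,14.96,15.45
female,75,14.34,14.81
female,76,13.73,14.18
female,77,13.13,13.56
female,78,12.54,12.94
female,79,11.95,12.34
female,80,11.38,11.75
female,81,10.82,11.17
female,82,10.26,10.6
female,83,9.72,10.03
female,84,9.18,9.48
female,85,8.66,8.94
female,86,8.14,8.41
female,87,7.64,7.89
female,88,7.15,7.38
female,89,6.66,6.88
female,90,6.19,6.4
female,91,5.74,5.92
female,92,5.29,5.46
female,93,4.85,5.01
female,94,4.43,4.58
female,95,4.02,4.15
female,96,3.63,3.75
female,97,3.25,3.35
female,98,2.88,2.97
female,99,2.53,2.61
female,100,2.19,2.26
male,0,74.5,77.1
male,1,73.49,76.05
male,2,72.48,75.01
male,3,71.47,73.97
male,4,70.47,72.93
male,5,69.48,71.9
male,6,68.49,70.88
male,7,67.5,69.86
male,8,66.52,68.84
male,9,65.55,67.83
male,10,64.58,66.83
male,11,63.61,65.83
male,12,62.65,64.83
male,13,61.69,63.84
male,14,60.74,62.86
male,15,59.79,61.88
male,16,58.85,60.91
male,17,57.92,59.94
male,18,56.98,58.97
male,19,56.06,58.01
male,20,55.14,57.06
male,21,54.22,56.11
male,22,53.31,55.17
male,23,52.4,54.23
male,24,51.5,53.3
male,25,50.61,52.37
male,26,49.71,51.45
male,27,48.83,50.53
male,28,47.95,49.62
male,29,47.08,48.72
male,30,46.21,47.82
male,31,45.34,46.93
male,32,44.48,46.04
male,33,43.63,45.15
male,34,42.78,44.28
male,35,41.94,43.41
male,36,41.11,42.54
male,37,40.28,41.68
male,38,39.45,40.83
male,39,38.63,39.98
male,40,37.82,39.14
male,41,37.01,38.3
male,42,36.21,37.47
male,43,35.41,36.65
male,44,34.62,35.83
male,45,33.84,35.02
male,46,33.06,34.22
male,47,32.29,33.42
male,48,31.52,32.63
male,49,30.77,31.84
male,50,30.01,31.06
male,51,29.26,30.29
male,52,28.52,29.52
male,53,27.79,28.76
male,54,27.06,28.01
male,55,26.34,27.26
male,56,25.62,26.52
male,57,24.92,25.79
male,58,24.21,25.06
male,59,23.52,24.34
male,60,22.83,23.63
male,61,22.15,22.92
male,62,21.47,22.22
male,63,20.81,21.53
male,64,20.15,20.85
male,65,19.49,20.17
male,66,18.85,19.5
male,67,18.21,18.84
male,68,17.58,18.19
male,69,16.95,17.54
male,70,16.34,16.91
male,71,15.73,16.28
male,72,15.13,15.65
male,73,14.53,15.04
male,74,13.95,14.44
male,75,13.37,13.84
male,76,12.8,13.25
male,77,12.24,12.67
male,78,11.69,12.1
male,79,11.15,11.53
male,80,10.61,10.98
male,81,10.08,10.44
male,82,9.57,9.9
male,83,9.06,9.38
male,84,8.56,8.86
male,85,8.07,8.35
male,86,7.59,7.86
male,87,7.12,7.37
male,88,6.66,6.9
male,89,6.21,6.43
male,90,5.78,5.98
male,91,5.35,5.53
male,92,4.93,5.1
male,93,4.53,4.68
male,94,4.13,4.28
male,95,3.75,3.88
male,96,3.38,3.5
male,97,3.03,3.13
male,98,2.68,2.78
male,99,2.36,2.44
male,100,2.04,2.11
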