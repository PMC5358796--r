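patient_id,age_years,sex,bmi,rheumatoid_arthritis,mean_oarsi,operated_knee
1,57,Female,35.6,no,3.4,Both
2,61,Female,36.1,no,3.7,Left
3,79,Male,27.8,no,4.3,Right
4,87,Female,22.3,no,5.1,Right
5,78,Female,27.6,no,4.2,Left
6,83,Female,26.5,no,4.3,Right
7,78,Female,28.7,no,3.9,Left
8,88,Female,30.2,no,3.8,Right
9,84,Female,25.0,no,4.4,Right
10,76,Female,25.9,no,3.6,Right (medial)
11,84,Female,34.4,no,4.2,Left
12,77,Male,26.0,no,4,Right
13,66,Female,26.2,no,4.1,Right
14,61,Female,33.3,no,4.4,Both
15,75,Female,34.1,no,4.6,Both
16,62,Female,30.2,no,4.7,Left
17,61,Female,33.3,no,4,Both
18,81,Female,34.6,yes,3.4,Right
19,70,Male,36.1,no,3.7,Left
20,82,Female,30.4,no,3.6,Right
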