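section,row,gender,term,count
age,13-15,male,skinny,38
age,13-15,male,thin,73
age,13-15,male,fat,277
age,13-15,male,obese,54
age,13-15,female,skinny,96
age,13-15,female,thin,253
age,13-15,female,fat,812
age,13-15,female,obese,105
age,16-18,male,skinny,22
age,16-18,male,thin,58
age,16-18,male,fat,319
age,16-18,male,obese,26
age,16-18,female,skinny,32
age,16-18,female,thin,148
age,16-18,female,fat,351
age,16-18,female,obese,43
age,19-25,male,skinny,10
age,19-25,male,thin,121
age,19-25,male,fat,271
age,19-25,male,obese,19
age,19-25,female,skinny,20
age,19-25,female,thin,87
age,19-25,female,fat,399
age,19-25,female,obese,39
age,25+,male,skinny,2
age,25+,male,thin,4
age,25+,male,fat,92
age,25+,male,obese,4
age,25+,female,skinny,4
age,25+,female,thin,24
age,25+,female,fat,113
age,25+,female,obese,10
adult_bmi,<18.5,male,skinny,4
adult_bmi,<18.5,male,thin,87
adult_bmi,<18.5,male,fat,3
adult_bmi,<18.5,male,obese,0
adult_bmi,<18.5,female,skinny,10
adult_bmi,<18.5,female,thin,23
adult_bmi,<18.5,female,fat,28
adult_bmi,<18.5,female,obese,0
adult_bmi,18.5-25,male,skinny,4
adult_bmi,18.5-25,male,thin,19
adult_bmi,18.5-25,male,fat,93
adult_bmi,18.5-25,male,obese,2
adult_bmi,18.5-25,female,skinny,7
adult_bmi,18.5-25,female,thin,44
adult_bmi,18.5-25,female,fat,236
adult_bmi,18.5-25,female,obese,6
adult_bmi,25-30,male,skinny,0
adult_bmi,25-30,male,thin,5
adult_bmi,25-30,male,fat,107
adult_bmi,25-30,male,obese,4
adult_bmi,25-30,female,skinny,2
adult_bmi,25-30,female,thin,10
adult_bmi,25-30,female,fat,78
adult_bmi,25-30,female,obese,7
adult_bmi,30+,male,skinny,0
adult_bmi,30+,male,thin,4
adult_bmi,30+,male,fat,83
adult_bmi,30+,male,obese,12
adult_bmi,30+,female,skinny,2
adult_bmi,30+,female,thin,11
adult_bmi,30+,female,fat,72
adult_bmi,30+,female,obese,26
teen_pct,<5,male,skinny,15
teen_pct,<5,male,thin,16
teen_pct,<5,male,fat,24
teen_pct,<5,male,obese,0
teen_pct,<5,female,skinny,18
teen_pct,<5,female,thin,46
teen_pct,<5,female,fat,62
teen_pct,<5,female,obese,1
teen_pct,5-85,male,skinny,42
teen_pct,5-85,male,thin,83
teen_pct,5-85,male,fat,334
teen_pct,5-85,male,obese,17
teen_pct,5-85,female,skinny,95
teen_pct,5-85,female,thin,311
teen_pct,5-85,female,fat,882
teen_pct,5-85,female,obese,52
teen_pct,85-95,male,skinny,4
teen_pct,85-95,male,thin,17
teen_pct,85-95,male,fat,156
teen_pct,85-95,male,obese,13
teen_pct,85-95,female,skinny,11
teen_pct,85-95,female,thin,45
teen_pct,85-95,female,fat,201
teen_pct,85-95,female,obese,37
teen_pct,95+,male,skinny,3
teen_pct,95+,male,thin,25
teen_pct,95+,male,fat,159
teen_pct,95+,male,obese,55
teen_pct,95+,female,skinny,7
teen_pct,95+,female,thin,22
teen_pct,95+,female,fat,116
teen_pct,95+,female,obese,68
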