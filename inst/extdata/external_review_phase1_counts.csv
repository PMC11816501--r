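chapter,polarity,answer,count
glycemic_management,PP,yes,151
glycemic_management,PP,no,92
glycemic_management,PP,not_sure,39
glycemic_management,PN,yes,1
glycemic_management,PN,no,11
glycemic_management,PN,not_sure,3
dyslipidemia,PP,yes,179
dyslipidemia,PP,no,70
dyslipidemia,PP,not_sure,33
dyslipidemia,PN,yes,2
dyslipidemia,PN,no,11
dyslipidemia,PN,not_sure,2
blood_pressure,PP,yes,144
blood_pressure,PP,no,92
blood_pressure,PP,not_sure,46
blood_pressure,PN,yes,1
blood_pressure,PN,no,11
blood_pressure,PN,not_sure,3
antiplatelet,PP,yes,82
antiplatelet,PP,no,5
antiplatelet,PP,not_sure,17
antiplatelet,PN,yes,2
antiplatelet,PN,no,2
antiplatelet,PN,not_sure,1
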