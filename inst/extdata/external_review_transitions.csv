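chapter,from,to,count
glycemic_management,no,yes,79
glycemic_management,no,missing,1
glycemic_management,not_sure,yes,33
glycemic_management,not_sure,no,3
glycemic_management,not_sure,missing,3
dyslipidemia,no,yes,66
dyslipidemia,no,not_sure,1
dyslipidemia,not_sure,yes,31
dyslipidemia,not_sure,no,2
blood_pressure,no,yes,82
blood_pressure,no,not_sure,2
blood_pressure,not_sure,yes,41
blood_pressure,not_sure,no,1
antiplatelet,no,yes,1
antiplatelet,no,not_sure,1
antiplatelet,not_sure,yes,5
antiplatelet,not_sure,no,10
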