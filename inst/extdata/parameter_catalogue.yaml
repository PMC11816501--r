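# Demonstration patient-parameter catalogue, version 1.0.
# Units follow Canadian convention: HbA1c in % (NGSP), lipids in mmol/L,
# eGFR in mL/min/1.73 m2, blood pressure in mmHg. Plausible ranges are
# configuration: unit-mismatched inputs surface as out_of_range issues.
version: "1.0"
parameters:
  - name: age
    kind: numeric
    unit: years
    range: [18, 110]
    chapters: [glycemic_management, dyslipidemia, blood_pressure, antiplatelet]
  - name: sex
    kind: categorical
    unit: ""
    values: [female, male]
    chapters: []
  - name: bmi
    kind: numeric
    unit: kg/m2
    range: [10, 70]
    chapters: []
  - name: hba1c
    kind: numeric
    unit: "%"
    range: [3, 20]
    chapters: [glycemic_management]
  - name: egfr
    kind: numeric
    unit: mL/min/1.73m2
    range: [0, 200]
    chapters: [glycemic_management, blood_pressure]
  - name: acr
    kind: numeric
    unit: mg/mmol
    range: [0, 300]
    chapters: []
  - name: ldl_c
    kind: numeric
    unit: mmol/L
    range: [0, 15]
    chapters: [dyslipidemia]
  - name: hdl_c
    kind: numeric
    unit: mmol/L
    range: [0, 5]
    chapters: []
  - name: non_hdl_c
    kind: numeric
    unit: mmol/L
    range: [0, 16]
    chapters: []
  - name: triglycerides
    kind: numeric
    unit: mmol/L
    range: [0, 30]
    chapters: []
  - name: sbp
    kind: numeric
    unit: mmHg
    range: [60, 250]
    chapters: [blood_pressure]
  - name: dbp
    kind: numeric
    unit: mmHg
    range: [30, 150]
    chapters: [blood_pressure]
  - name: potassium
    kind: numeric
    unit: mmol/L
    range: [2, 8]
    chapters: [blood_pressure]
  - name: ascvd
    kind: boolean
    unit: ""
    chapters: [glycemic_management, dyslipidemia, blood_pressure, antiplatelet]
  - name: hf
    kind: boolean
    unit: ""
    chapters: [glycemic_management]
  - name: ckd
    kind: boolean
    unit: ""
    chapters: [glycemic_management, blood_pressure]
  - name: metabolic_decompensation
    kind: boolean
    unit: ""
    chapters: [glycemic_management]
  - name: symptomatic_hyperglycemia
    kind: boolean
    unit: ""
    chapters: [glycemic_management]
  - name: pregnancy
    kind: boolean
    unit: ""
    chapters: [glycemic_management, dyslipidemia, blood_pressure]
  - name: bleeding_risk
    kind: boolean
    unit: ""
    chapters: [antiplatelet]
  - name: frailty
    kind: boolean
    unit: ""
    chapters: [glycemic_management]
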