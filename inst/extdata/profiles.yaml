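# Analyte population profiles of an outpatient primary-care laboratory.
# Units: creatinine umol/L, potassium and sodium mmol/L, albumin g/L.
# tea_percent is the CLIA allowable total error used as the clinically
# significant bias size.
profiles:
  - name: creatinine
    unit: umol/L
    daily_volume: 121
    median: 70
    q1: 63
    q3: 80
    min_value: 26
    max_value: 971
    skew_family: right_tailed
    outlier_rate: 0.01
    tea_percent: 15
  - name: potassium
    unit: mmol/L
    daily_volume: 60
    median: 4.3
    q1: 4.1
    q3: 4.6
    min_value: 2.8
    max_value: 7.4
    skew_family: symmetric
    outlier_rate: 0.01
    tea_percent: 17.97
  - name: sodium
    unit: mmol/L
    daily_volume: 55
    median: 140
    q1: 139
    q3: 141
    min_value: 123
    max_value: 149
    skew_family: symmetric
    outlier_rate: 0.01
    tea_percent: 3.57
  - name: albumin
    unit: g/L
    daily_volume: 20
    median: 43
    q1: 41
    q3: 44
    min_value: 20
    max_value: 52
    skew_family: left_tailed
    outlier_rate: 0.01
    tea_percent: 10
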