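mode: untruncated
within_group_correlation: 0.0
groups:
  CU:
    'n': 133
    male_proportion: 0.443609
    means:
      age: 72.15
      education_years: 7.38
      cdr_sb: 0.35
      npi_sb: 2.64
      iadl: 7.79
      casi: 83.86
      mmse: 25.81
      moca: 21.07
      haisac_total: 48.47
      haisac3: 33.95
      haisaci: 14.53
      cnocd: 14.85
      ml: 9.04
      rfo: 10.06
      cd: 2.71
      fd: 11.82
    sds:
      age: 7.38
      education_years: 4.76
      cdr_sb: 0.32
      npi_sb: 3.45
      iadl: 0.55
      casi: 8.64
      mmse: 3.3
      moca: 5.1
      haisac_total: 6.58
      haisac3: 4.53
      haisaci: 4.19
      cnocd: 1.69
      ml: 3.07
      rfo: 1.57
      cd: 3.8
      fd: 1.4586295
  MCI:
    'n': 231
    male_proportion: 0.3852814
    means:
      age: 74.9
      education_years: 5.78
      cdr_sb: 1.96
      npi_sb: 4.42
      iadl: 6.58
      casi: 73.12
      mmse: 22.24
      moca: 15.99
      haisac_total: 38.94
      haisac3: 29.77
      haisaci: 9.18
      cnocd: 13.88
      ml: 6.83
      rfo: 9.06
      cd: 0.76
      fd: 8.42
    sds:
      age: 7.29
      education_years: 4.43
      cdr_sb: 2.16
      npi_sb: 6.06
      iadl: 2.03
      casi: 15.93
      mmse: 5.2
      moca: 6.33
      haisac_total: 10.53
      haisac3: 6.94
      haisaci: 6.36
      cnocd: 2.32
      ml: 4.17
      rfo: 2.07
      cd: 2.35
      fd: 5.4903188
  DAT:
    'n': 397
    male_proportion: 0.2997481
    means:
      age: 81.17
      education_years: 4.27
      cdr_sb: 7.17
      npi_sb: 6.16
      iadl: 2.2
      casi: 44.83
      mmse: 13.98
      moca: 7.21
      haisac_total: 21.51
      haisac3: 19.42
      haisaci: 2.09
      cnocd: 10.54
      ml: 2.51
      rfo: 6.37
      cd: 0.12
      fd: 1.97
    sds:
      age: 7.81
      education_years: 4.53
      cdr_sb: 4.58
      npi_sb: 9.18
      iadl: 2.53
      casi: 22.7
      mmse: 6.55
      moca: 5.4
      haisac_total: 11.29
      haisac3: 9.27
      haisaci: 4.71
      cnocd: 4.37
      ml: 3.55
      rfo: 3.29
      cd: 0.98
      fd: 4.4451209
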