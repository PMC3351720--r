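PMID- 90000001
TI  - Permanent seed brachytherapy for localized prostate cancer: synthetic
      record for package examples.
AB  - Synthetic abstract. Patients with localized prostate adenocarcinoma
      treated with permanent iodine seed implantation were followed for
      biochemical recurrence using serum PSA measurements.
MH  - Prostatic Neoplasms/radiotherapy
MH  - Brachytherapy/methods
MH  - Humans
MH  - Male

PMID- 90000002
TI  - External beam radiotherapy compared with brachytherapy in prostate
      cancer: a synthetic comparison.
AB  - Synthetic abstract. Outcomes after external beam radiation therapy and
      interstitial brachytherapy were compared in patients with clinically
      localized prostate cancer and intermediate Gleason scores.
MH  - Prostatic Neoplasms/radiotherapy
MH  - *Brachytherapy
MH  - Radiotherapy, Conformal

PMID- 90000003
TI  - Radical prostatectomy outcomes in a synthetic cohort.
AB  - Synthetic abstract. Men undergoing radical prostatectomy for prostate
      adenocarcinoma were assessed for surgical margins and prostate-specific
      antigen relapse.
MH  - Prostatectomy
MH  - Prostatic Neoplasms/surgery
MH  - Prostate-Specific Antigen/blood

PMID- 90000004
TI  - Quality of life after permanent implant brachytherapy: synthetic survey
      data.
AB  - Synthetic abstract. Urinary and bowel quality of life after permanent
      seed implantation for prostate cancer was surveyed at twelve months.
MH  - Brachytherapy/adverse effects
MH  - Quality of Life
MH  - Prostatic Neoplasms

PMID- 90000005
TI  - Hip fracture fixation in the elderly: an unrelated synthetic control
      record.
AB  - Synthetic abstract. Internal fixation versus arthroplasty for femoral
      neck fractures in elderly patients.
MH  - Hip Fractures/surgery
MH  - Aged

PMID- 90000006
TI  - Asthma inhaler adherence: an unrelated synthetic control record.
AB  - Synthetic abstract. Adherence to inhaled corticosteroids among adults
      with persistent asthma in primary care.
MH  - Asthma/drug therapy
MH  - Medication Adherence
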