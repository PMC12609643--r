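# Default synthetic-cohort generator parameters: published descriptive
# statistics of the three-group rabbit SAH experiment.
# Units: pupil diameter in micrometres; DADA index dimensionless;
# degenerated EWN neuron density in n/mm^3.
control:
  group: control
  "n": 5
  pupil_diameter_mean: 5900.00
  pupil_diameter_sd: 546.32
  pupil_diameter_min: 5200.00
  pupil_diameter_max: 6600.00
  dada_mean: 2.32
  dada_sd: 0.43
  dada_min: 1.78
  dada_max: 2.90
  degen_mean: 3.00
  degen_sd: 0.95
  degen_min: 1.80
  degen_max: 4.20
sham:
  group: sham
  "n": 5
  pupil_diameter_mean: 6310.00
  pupil_diameter_sd: 533.35
  pupil_diameter_min: 5452.00
  pupil_diameter_max: 6850.00
  dada_mean: 1.95
  dada_sd: 0.37
  dada_min: 1.47
  dada_max: 2.41
  degen_mean: 12.00
  degen_sd: 2.92
  degen_min: 8.20
  degen_max: 15.80
study:
  group: study
  "n": 12
  pupil_diameter_mean: 9989.50
  pupil_diameter_sd: 747.12
  pupil_diameter_min: 8780.00
  pupil_diameter_max: 11138.00
  dada_mean: 1.06
  dada_sd: 0.31
  dada_min: 0.58
  dada_max: 1.65
  degen_mean: 18.00
  degen_sd: 4.00
  degen_min: 11.00
  degen_max: 25.00
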