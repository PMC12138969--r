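toxicity_csv: synthetic_toxicity.csv
reference_series:
  Insecta: synthetic_reference_insecta.csv
  Malacostraca: synthetic_reference_malacostraca.csv
  Branchiopoda: synthetic_reference_branchiopoda.csv
class_map:
  Insecta: Insecta
  Malacostraca: Malacostraca
  Branchiopoda: Branchiopoda
calibration:
  Insecta:
    ec_measured: 31.7757922
    measured_day: 4.0
  Malacostraca:
    ec_measured: 143.9931319
    measured_day: 4.0
  Branchiopoda:
    ec_measured: 26.9433286
    measured_day: 2.0
acr_table_csv: synthetic_acr_table.csv
acr_defaults:
- 10.0
- 50.0
- 100.0
protection_levels:
- 99.0
- 95.0
- 90.0
- 80.0
days:
- 1.0
- 100.0
n_boot_pc: 0.0
n_boot_regression: 1000.0
seed: 20260101
out_dir: trs_output
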