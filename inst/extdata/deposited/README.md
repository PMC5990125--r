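# Deposited tables (not bundled)

The reproduction checks in `reproduce_deposited_results()` and the
acceptance suite read the three publicly deposited tables of the study
cohort from this directory. They are distributed by the journal's data
repository under a CC0 waiver and are not bundled with the package;
download them and place them here, either as the original XLSX files or
(preferred) converted to CSV:

- `TrueOutcomes.csv` - one row per clinical record: a record-index column
  plus binary `T_180`, `T_360`, `T_720` outcome labels.
- `Student_Predictions.csv` - either the questionnaire block layout of the
  deposited workbook or, preferred, the long layout with columns
  `rater_id`, `record_id`, `horizon`, `score` (integer 0-5).
- `RF_Predictions.csv` - one row per record: a record-index column plus
  `Score_180`, `Score_360`, `Score_720` probabilities in [0, 1].

Record numbering must be consistent across the three files.
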