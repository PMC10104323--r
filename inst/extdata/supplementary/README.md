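Drop-in location for the raw per-plant supplementary tables of the
published screen, converted to the canonical tidy CSV (see
`kscreen::trial_columns()`) as `trial.csv`. The originals are distributed
as ODT spreadsheets alongside the article and are not bundled here; the
supplementary-reproduction acceptance test runs only when the converted
file is present.
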