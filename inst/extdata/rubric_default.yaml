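# Default ABB rubric cutoffs; keys mirror abb_cutoffs() arguments.
sn_n_min: 26        # cm, sternal notch-to-nipple
n_imf_min: 14       # cm, nipple-to-inframammary fold
bw_min: 16          # cm, base width
ptosis_qualifying_grade: 3   # Regnault grade, strict equality
symptom_points: 1
finding_points: 1
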