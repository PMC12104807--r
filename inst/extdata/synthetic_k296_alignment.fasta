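>REF_RHO synthetic reference; lysine at ungapped position 16 (alignment column 17)
MVTQFS-MLAAYMFLLKAVADLF-
>seq_complete_K synthetic; retains the homologous lysine
MVSQFSAMLATYMFLLKAVADLFM
>solenofilomorpha_sp9_like synthetic; complete but lysine substituted by R
MVTQFSAMLAAYMFLLRAVADLFM
>nadina_sp2_like synthetic; truncated before the lysine column
MVTQFSAMLAAYM-----------
>seq_internal_gap synthetic; alignment gap at the lysine column, flanked both sides
MVTQFSAMLAAYMF---LAVADLF
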