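>AGS_SH3_reference_synthetic offset=1086
VTLFVALYDCARDGELSLRKGDQVRILSNNKSGEWWEAASLTTGQEGLVPSNYIFVNSLEK
>SEM5_like_synthetic
VTLFVALYDFARQGELSLRKGDQVRILSNNKSGEWWEAASLTTGQEGLVPSNYIFVNSLEK
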