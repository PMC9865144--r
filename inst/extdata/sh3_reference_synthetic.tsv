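sequence	groove_center	acidic	aromatics	offset
VTLFVALYDCARDGELSLRKGDQVRILSNNKSGEWWEAASLTTGQEGLVPSNYIFVNSLEK	10	13	8,36,53,55	1086
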