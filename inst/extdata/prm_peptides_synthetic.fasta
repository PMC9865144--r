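>MICAL1_PRM_synthetic offset=827
ALPAKPARS
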