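# root: C0
C0 C1
C1 C2
C2 C0
C2 C3
C3 C4
C4 C0
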